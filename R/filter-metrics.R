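#' Complex frequency response of an IIR filter
#'
#' Evaluates `H(e^{i w}) = B(e^{-i w}) / A(e^{-i w})` by direct polynomial
#' evaluation on a linear grid from 0 to Nyquist.
#'
#' @param coeffs a `filter_coefficients` object
#' @param n_points number of grid points (>= 64)
#' @return a `frequency_response`: list with `grid` (Hz), `H` (complex),
#'   `magnitude_db`, `phase_unwrapped` (rad) and `group_delay` (samples)
#' @export
frequency_response <- function(coeffs, n_points = 512) {
  stopifnot(inherits(coeffs, "filter_coefficients"), n_points >= 64)
  grid <- seq(0, coeffs$fs / 2, length.out = n_points)
  w <- 2 * pi * grid / coeffs$fs
  H <- polyval_dtft(coeffs$b, w) / polyval_dtft(coeffs$a, w)
  structure(list(grid = grid,
                 H = H,
                 magnitude_db = 20 * log10(pmax(Mod(H), 1e-300)),
                 phase_unwrapped = as.numeric(signal::unwrap(Arg(H))),
                 group_delay = group_delay(coeffs, grid),
                 fs = coeffs$fs),
            class = "frequency_response")
}

# Sum_k p[k+1] e^{-i w k}
polyval_dtft <- function(p, w) {
  k <- seq_along(p) - 1
  ew <- exp(outer(-1i * w, k))
  as.vector(ew %*% p)
}

#' Group delay of an IIR filter in samples
#'
#' The negative derivative of the unwrapped phase with respect to the
#' normalized frequency, computed analytically from the coefficient
#' polynomials (derivative of the log-DTFT of numerator and denominator).
#' Grid points coinciding with exact response zeros, where the phase is
#' undefined, are returned as `NA` with a warning.
#'
#' @param coeffs a `filter_coefficients` object
#' @param grid frequencies in Hz within (0, Nyquist]
#' @return group delay in samples at each grid frequency
#' @export
group_delay <- function(coeffs, grid) {
  stopifnot(inherits(coeffs, "filter_coefficients"))
  w <- 2 * pi * grid / coeffs$fs
  gd_poly <- function(p) {
    P <- polyval_dtft(p, w)
    k <- seq_along(p) - 1
    dP <- polyval_dtft(p * k, w)        # Sum k p_k e^{-iwk}
    list(val = P, gd = Re(dP / P))
  }
  num <- gd_poly(coeffs$b)
  den <- gd_poly(coeffs$a)
  out <- num$gd - den$gd
  bad <- Mod(num$val) < 1e-12
  if (any(bad)) {
    warning("group delay undefined at ", sum(bad),
            " grid point(s) coinciding with response zeros")
    out[bad] <- NA_real_
  }
  out
}

#' Poles, zeros and gain of an IIR filter
#'
#' @param coeffs a `filter_coefficients` object
#' @return a `pole_zero_set`: list with `zeros`, `poles` (complex), `gain`
#'   (b0/a0 leading ratio) and `stable` (all pole moduli < 1)
#' @export
pole_zero <- function(coeffs) {
  stopifnot(inherits(coeffs, "filter_coefficients"))
  if (all(coeffs$b == 0)) stop("degenerate all-zero numerator")
  # polyroot takes ascending powers; coefficients are stored b0..bM (powers
  # of z^-1), so roots in z are those of the reversed polynomial
  zeros <- polyroot(rev(coeffs$b))
  poles <- polyroot(rev(coeffs$a))
  structure(list(zeros = zeros, poles = poles,
                 gain = coeffs$b[1] / coeffs$a[1],
                 stable = all(Mod(poles) < 1)),
            class = "pole_zero_set")
}

#' @export
print.pole_zero_set <- function(x, ...) {
  cat(sprintf("<pole_zero_set> %d zeros, %d poles, %s\n", length(x$zeros),
              length(x$poles), if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Passband ripple and transition widths from a frequency response
#'
#' Ripple is the max-min magnitude span (dB) between the outermost local
#' gain maxima inside the passband: a monotone (maximally flat) response
#' has at most one interior maximum and reports 0, while an equiripple
#' response reports its design ripple, uncontaminated by the -3 dB edge
#' roll-off. Each transition width is the distance from the -3 dB point at
#' the band edge to the first crossing of `-atten_db` beyond it. If a
#' crossing is never reached before the grid limit the width is reported
#' as `Inf` with a warning.
#'
#' @param resp a [frequency_response()]
#' @param passband `c(f_lo, f_hi)` in Hz
#' @param atten_db attenuation (dB > 3) defining the stopband edge
#' @return list with `ripple_db`, `f_low_tw`, `f_high_tw`
#' @export
band_metrics <- function(resp, passband, atten_db = 20) {
  stopifnot(inherits(resp, "frequency_response"), atten_db > 3,
            passband[1] < passband[2], passband[2] <= max(resp$grid))
  g <- resp$grid
  mag <- resp$magnitude_db
  in_pb <- which(g >= passband[1] & g <= passband[2])
  m <- mag[in_pb]
  # local maxima of the in-band magnitude; the span between the outermost
  # ones is the equiripple band (empty or a point for monotone responses)
  lm <- which(diff(sign(diff(m))) < 0) + 1
  ripple <- if (length(lm) >= 2) {
    seg <- m[lm[1]:lm[length(lm)]]
    max(seg) - min(seg)
  } else 0
  ref <- max(m)
  edge3 <- function(side) {
    # -3 dB crossing nearest the band edge, searched outward from the band
    if (side == "low") {
      i <- which(g <= passband[1] + diff(passband) / 2)
      j <- rev(i)[which(mag[rev(i)] <= ref - 3)][1]
    } else {
      i <- which(g >= passband[1] + diff(passband) / 2)
      j <- i[which(mag[i] <= ref - 3)][1]
    }
    if (is.na(j)) NA_real_ else g[j]
  }
  cross <- function(side, from) {
    if (is.na(from)) return(NA_real_)
    if (side == "low") {
      i <- which(g <= from)
      j <- rev(i)[which(mag[rev(i)] <= ref - atten_db)][1]
    } else {
      i <- which(g >= from)
      j <- i[which(mag[i] <= ref - atten_db)][1]
    }
    if (is.na(j)) {
      warning("no -", atten_db, " dB crossing on the ", side,
              " side; transition width unbounded on this grid")
      Inf
    } else abs(g[j] - from)
  }
  f3_lo <- edge3("low"); f3_hi <- edge3("high")
  list(ripple_db = ripple,
       f_low_tw = cross("low", f3_lo),
       f_high_tw = cross("high", f3_hi))
}

#' Spectral fidelity of a zero-phase filter against an ideal bandpass
#'
#' Scores how closely the effective (zero-phase, i.e. squared single-pass)
#' magnitude response approximates a brick-wall bandpass with unit gain in
#' `band` and zero gain outside:
#' `SF = (1 - sum((H_ideal - H_actual)^2) / sum(H_ideal^2)) * 100`,
#' evaluated on a linear K-point grid from 0 to Nyquist. `sf_normalized`
#' rescales so that a chosen reference configuration reads 100.
#'
#' @param coeffs a `filter_coefficients` object
#' @param band passband `c(f_lo, f_hi)` in Hz (default 0.8-20)
#' @param K number of grid points (>= 1024; default 4096)
#' @param reference optional `filter_coefficients` of the reference
#'   configuration whose raw score defines 100 on the normalized scale
#' @return a `fidelity_report`: list with `sf_raw`, `sf_normalized`,
#'   `K`, `band`
#' @export
spectral_fidelity <- function(coeffs, band = c(0.8, 20), K = 4096,
                              reference = NULL) {
  stopifnot(inherits(coeffs, "filter_coefficients"), K >= 1024)
  if (band[1] >= band[2]) stop("empty passband")
  raw <- function(cf) {
    grid <- seq(0, cf$fs / 2, length.out = K)
    w <- 2 * pi * grid / cf$fs
    Hm <- Mod(polyval_dtft(cf$b, w) / polyval_dtft(cf$a, w))^2  # zero-phase
    Hi <- as.numeric(grid >= band[1] & grid <= band[2])
    (1 - sum((Hi - Hm)^2) / sum(Hi^2)) * 100
  }
  sf <- raw(coeffs)
  sf_norm <- if (is.null(reference)) sf else sf / raw(reference) * 100
  structure(list(sf_raw = sf, sf_normalized = sf_norm, K = K, band = band),
            class = "fidelity_report")
}
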