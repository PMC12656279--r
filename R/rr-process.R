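#' Specify a ground-truth RR-interval process
#'
#' Describes the beat-to-beat interval dynamics used to synthesize paired
#' recordings: a mean RR interval plus a sum of spectral components, each a
#' sinusoid or band-limited noise centered on a chosen frequency. With
#' sinusoidal components and no noise the band powers of the resulting
#' tachogram are analytically known (amplitude^2 / 2 falls into the band
#' containing the component frequency), which is what makes the downstream
#' spectral pipeline testable against closed-form truth.
#'
#' @param mean_rr mean RR interval in ms (>= 300)
#' @param components list of components, each `list(freq =, amplitude =,
#'   kind =)` with `freq` in Hz (0 < freq <= 0.5), `amplitude` in ms and
#'   `kind` one of `"sinusoid"` or `"band-limited-noise"`. For noise
#'   components the amplitude is matched in RMS power to a sinusoid of the
#'   same amplitude.
#' @param duration segment length in seconds
#' @param seed integer seed controlling component phases / noise draws
#' @return an `rr_process_spec`
#' @export
rr_process_spec <- function(mean_rr = 1000,
                            components = list(),
                            duration = 150,
                            seed = 1) {
  stopifnot(mean_rr >= 300, duration > 0)
  for (cmp in components) {
    stopifnot(is.list(cmp), cmp$freq > 0, cmp$freq <= 0.5, cmp$amplitude >= 0)
    if (!cmp$kind %in% c("sinusoid", "band-limited-noise"))
      stop("component kind must be 'sinusoid' or 'band-limited-noise'")
  }
  structure(list(mean_rr = mean_rr, components = components,
                 duration = duration, seed = as.integer(seed)),
            class = "rr_process_spec")
}

# Instantaneous RR modulation (ms) on a fine time grid.
rr_modulation <- function(spec, t) {
  rr <- rep(spec$mean_rr, length(t))
  for (i in seq_along(spec$components)) {
    cmp <- spec$components[[i]]
    if (cmp$amplitude == 0) next
    if (cmp$kind == "sinusoid") {
      phase <- with_seed(derive_seed(spec$seed, 101, i),
                         stats::runif(1, 0, 2 * pi))
      rr <- rr + cmp$amplitude * sin(2 * pi * cmp$freq * t + phase)
    } else {
      # white noise narrowband-filtered around the center frequency, scaled
      # to the RMS of a sinusoid with the same nominal amplitude
      dt <- t[2] - t[1]
      fsg <- 1 / dt
      w <- with_seed(derive_seed(spec$seed, 102, i),
                     stats::rnorm(length(t)))
      half_bw <- 0.25 * cmp$freq
      edges <- c(max(cmp$freq - half_bw, 1e-4), cmp$freq + half_bw) / (fsg / 2)
      bf <- signal::butter(2, edges, type = "pass")
      y <- as.numeric(signal::filter(bf, w))
      y <- y / stats::sd(y) * cmp$amplitude / sqrt(2)
      rr <- rr + y
    }
  }
  rr
}

#' Generate beat times by integral pulse frequency modulation
#'
#' Realizes the RR process as an IPFM generator: the instantaneous rate
#' 1/RR(t) is integrated and a beat is emitted each time the integral
#' crosses an integer threshold. The first beat is at t = 0. For a constant
#' RR the beats are exactly periodic; for sinusoidal modulation the
#' tachogram inherits the component spectrum, so band powers are known in
#' closed form.
#'
#' @param spec an [rr_process_spec()]
#' @param dt integration step in seconds (default 5 ms)
#' @return strictly increasing beat times in seconds (first at 0)
#' @export
generate_rr_series <- function(spec, dt = 0.005) {
  stopifnot(inherits(spec, "rr_process_spec"))
  t <- seq(0, spec$duration, by = dt)
  rr <- rr_modulation(spec, t)
  if (any(rr < 300))
    stop("RR modulation drives the instantaneous interval below 300 ms; ",
         "reduce component amplitudes")
  rate <- 1000 / rr                      # beats per second
  # trapezoidal cumulative integral of the rate
  integ <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))
  n_beats <- floor(integ[length(integ)])
  if (n_beats < 1) stop("duration too short for a single beat")
  ks <- seq_len(n_beats)
  idx <- findInterval(ks, integ)         # integ[idx] <= k < integ[idx + 1]
  idx <- pmin(idx, length(integ) - 1L)   # guard: threshold hit exactly at end
  frac <- (ks - integ[idx]) / (integ[idx + 1] - integ[idx])
  frac[!is.finite(frac)] <- 0
  beats <- c(0, t[idx] + frac * dt)
  stopifnot(all(diff(beats) > 0))
  beats
}

#' Analytic band powers implied by a sinusoid-only RR process
#'
#' For each component, amplitude^2 / 2 (ms^2) is assigned to the standard
#' HRV band containing its center frequency. Beat intervals are averages of
#' the instantaneous modulation over one beat, so the measured tachogram
#' attenuates a component at frequency f by sinc(pi f T) in amplitude
#' (T = mean RR); with `interval_sampled = TRUE` (default) the returned
#' powers carry this sinc^2 factor and are what the full
#' detection-spectral pipeline is expected to recover. Only meaningful for
#' specs with sinusoidal components.
#'
#' @param spec an [rr_process_spec()]
#' @param interval_sampled apply the beat-averaging sinc^2 attenuation
#' @return named numeric vector `c(vlf =, lf =, hf =)` in ms^2
#' @export
analytic_band_powers <- function(spec, interval_sampled = TRUE) {
  out <- c(vlf = 0, lf = 0, hf = 0)
  bands <- hrv_bands()
  for (cmp in spec$components) {
    p <- cmp$amplitude^2 / 2
    if (interval_sampled) {
      xx <- pi * cmp$freq * spec$mean_rr / 1000
      p <- p * (sin(xx) / xx)^2
    }
    for (b in names(bands)) {
      if (cmp$freq >= bands[[b]][1] && cmp$freq < bands[[b]][2])
        out[b] <- out[b] + p
    }
  }
  out
}
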