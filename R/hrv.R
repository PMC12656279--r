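#' Standard frequency-domain HRV bands
#'
#' Very-low (0.0033-0.04 Hz), low (0.04-0.15 Hz) and high (0.15-0.40 Hz)
#' frequency bands. Bins are assigned by half-open `[lo, hi)` membership of
#' bin centers, so a boundary bin at 0.04 Hz belongs to LF and one at 0.15
#' Hz to HF (no double counting).
#'
#' @return named list of `c(lo, hi)` in Hz
#' @export
hrv_bands <- function() {
  list(vlf = c(0.0033, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.40))
}

new_beat_series <- function(peak_times, source) {
  stopifnot(all(diff(peak_times) > 0))
  structure(list(peak_times = peak_times,
                 intervals = diff(peak_times) * 1000,
                 source = source),
            class = "beat_series")
}

# Enforce the physiological floor: drop any detection closer than 300 ms to
# the previously accepted one (keeping the earlier detection).
enforce_refractory <- function(times, heights = NULL, floor_s = 0.3) {
  if (length(times) == 0) return(times)
  keep <- times[1]
  for (k in seq_along(times)[-1]) {
    if (times[k] - keep[length(keep)] >= floor_s) keep <- c(keep, times[k])
  }
  keep
}

#' Detect ECG R-peaks (Pan-Tompkins)
#'
#' Classic stage sequence: bandpass emphasis (5-15 Hz), five-point
#' derivative, squaring, moving-window integration (150 ms), then adaptive
#' signal/noise thresholds with the original 200 ms lockout. Detections are
#' mapped back to the local maximum of the bandpassed ECG, and the 300 ms
#' physiological interval floor is enforced on the final series.
#'
#' @param x a preprocessed ECG [hrv_signal()] at 1000 Hz (see
#'   [preprocess_ecg()]); other rates are accepted for the stage logic but
#'   the study's reference channel is 1000 Hz
#' @return a `beat_series` with `source = "ecg"`
#' @export
detect_ecg_rpeaks <- function(x) {
  stopifnot(inherits(x, "hrv_signal"))
  fs <- x$fs
  st <- pan_tompkins_stages(x)
  peaks_i <- adaptive_threshold_peaks(st$mwi, fs)
  if (length(peaks_i) < 2) stop("fewer than 2 beats detected: no intervals")
  # locate the R wave as the max of the (zero-phase preprocessed) input in
  # the 200 ms window preceding each integration peak: the MWI and the
  # causal emphasis stages lag the QRS, the input does not
  win <- round(0.2 * fs)
  r_i <- vapply(peaks_i, function(i) {
    lo <- max(1L, as.integer(i) - win)
    as.integer(lo - 1L + which.max(x$samples[lo:i]))
  }, integer(1))
  r_i <- sort(unique(r_i))
  times <- enforce_refractory(x$t0 + (r_i - 1) / fs)
  if (length(times) < 2) stop("fewer than 2 beats detected: no intervals")
  new_beat_series(times, "ecg")
}

# Pan-Tompkins front-end stages, exposed for stage-by-stage verification.
pan_tompkins_stages <- function(x) {
  fs <- x$fs
  bp <- design_butterworth_bandpass(
    filter_spec("butterworth", spec_order = 1, f_lo = 5, f_hi = 15, fs = fs))
  bandpassed <- as.numeric(signal::filter(bp$b, bp$a, x$samples))
  # five-point derivative, gain fs/8
  dkern <- c(1, 2, 0, -2, -1) * fs / 8
  deriv <- as.numeric(stats::filter(bandpassed, dkern, sides = 1))
  deriv[is.na(deriv)] <- 0
  squared <- deriv^2
  nw <- round(0.15 * fs)
  mwi <- as.numeric(stats::filter(squared, rep(1 / nw, nw), sides = 1))
  mwi[is.na(mwi)] <- 0
  list(bandpassed = bandpassed, derivative = deriv, squared = squared,
       mwi = mwi)
}

# Adaptive signal/noise-level thresholding on the integrated waveform with
# the original 200 ms lockout; returns accepted candidate indices.
adaptive_threshold_peaks <- function(mwi, fs) {
  n <- length(mwi)
  cand <- which(diff(sign(diff(mwi))) < 0) + 1    # local maxima
  cand <- cand[mwi[cand] > 0]
  if (length(cand) == 0) return(integer(0))
  # initialize from the first two seconds
  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  lockout <- round(0.2 * fs)
  accepted <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (i - last <= lockout) {
      # within lockout: keep the larger of the competing candidates
      if (length(accepted) && mwi[i] > mwi[accepted[length(accepted)]] &&
          i - (if (length(accepted) > 1) accepted[length(accepted) - 1] else -Inf) > lockout) {
        accepted[length(accepted)] <- i
        last <- i
        spki <- 0.125 * mwi[i] + 0.875 * spki
      }
      next
    }
    if (mwi[i] >= thr) {
      accepted <- c(accepted, i)
      last <- i
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  accepted
}

#' Detect PPG pulse peaks
#'
#' Finds local maxima of the zero-phase bandpassed PPG exceeding an
#' adaptive prominence threshold (a fraction of the median upper-decile
#' peak height), with the 300 ms physiological refractory period; within a
#' refractory conflict the lower peak is rejected. Peak times are refined
#' by parabolic interpolation through the three samples around each
#' maximum, so detection parameters and behavior are identical across
#' sampling rates. The waveform maximum is the fiducial.
#'
#' @param x a zero-phase bandpassed PPG [hrv_signal()]
#' @param threshold_frac fraction of the reference peak height a maximum
#'   must exceed (default 0.4)
#' @return a `beat_series` with `source = "ppg"`
#' @export
detect_ppg_peaks <- function(x, threshold_frac = 0.4) {
  stopifnot(inherits(x, "hrv_signal"))
  s <- x$samples
  if (max(s) - min(s) < 1e-12) stop("flat signal: no pulses detectable")
  cand <- which(diff(sign(diff(s))) < 0) + 1
  if (length(cand) == 0) stop("no local maxima found")
  # anchor the amplitude reference to the tallest maxima, taking as many as
  # the slowest plausible heart rate (~43 bpm) would produce, so noise
  # bumps cannot drag the threshold down
  m <- max(3L, floor(length(s) / x$fs / 1.4))
  tall <- utils::head(sort(s[cand], decreasing = TRUE), m)
  ref_height <- stats::median(tall)
  thr <- threshold_frac * ref_height
  cand <- cand[s[cand] >= thr]
  if (length(cand) < 2) stop("fewer than 2 pulses detected")
  # refractory with larger-peak preference
  keep <- integer(0)
  floor_n <- 0.3 * x$fs
  for (i in cand) {
    if (length(keep) == 0 || i - keep[length(keep)] >= floor_n) {
      keep <- c(keep, i)
    } else if (s[i] > s[keep[length(keep)]]) {
      prev_ok <- length(keep) < 2 || i - keep[length(keep) - 1] >= floor_n
      if (prev_ok) keep[length(keep)] <- i
    }
  }
  if (length(keep) < 2) stop("fewer than 2 pulses detected")
  # parabolic sub-sample refinement
  times <- vapply(keep, function(i) {
    if (i <= 1 || i >= length(s)) return(x$t0 + (i - 1) / x$fs)
    y1 <- s[i - 1]; y2 <- s[i]; y3 <- s[i + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) < 1e-30) 0 else 0.5 * (y1 - y3) / denom
    delta <- max(min(delta, 0.5), -0.5)
    x$t0 + (i - 1 + delta) / x$fs
  }, numeric(1))
  new_beat_series(enforce_refractory(times), "ppg")
}

#' Convert a beat series to a uniformly resampled tachogram
#'
#' Knots are placed at beat times (each carrying the NN interval ending at
#' that beat); a natural cubic spline through the knots is sampled on a
#' uniform 4 Hz grid spanning the segment, giving `round(duration * 4)`
#' values (600 for a 2.5 min segment).
#'
#' @param beats a `beat_series` (>= 4 beats)
#' @param duration segment length in seconds
#' @param fs_resample resampling rate in Hz (4 by convention)
#' @return a `tachogram`: list with `knot_times` (s), `knot_values` (ms),
#'   `resampled` (ms), `times` (s), `duration`, `fs`
#' @export
beats_to_tachogram <- function(beats, duration, fs_resample = 4) {
  stopifnot(inherits(beats, "beat_series"))
  kt <- beats$peak_times[-1]
  kv <- beats$intervals
  if (length(kt) < 4) stop("need at least 4 beats for cubic spline interpolation")
  n <- round(duration * fs_resample)
  tt <- (seq_len(n) - 1) / fs_resample
  sp <- stats::spline(kt, kv, xout = tt, method = "natural")
  structure(list(knot_times = kt, knot_values = kv,
                 resampled = sp$y, times = tt,
                 duration = duration, fs = fs_resample),
            class = "tachogram")
}

#' Welch power spectral density of a tachogram
#'
#' 256-sample epochs with 128-sample (50%) overlap; each epoch is mean-
#' removed, Hann-windowed (with window power normalization) and transformed
#' with a 1024-point FFT; the one-sided densities are averaged across
#' epochs. Units are ms^2/Hz on a grid from 0 to 2 Hz with spacing
#' 4/1024 Hz. Trailing samples that do not fill an epoch are discarded.
#'
#' @param tach a [beats_to_tachogram()] result (>= 256 resampled samples)
#' @param nperseg epoch length (default 256)
#' @param noverlap epoch overlap (default 128)
#' @param nfft transform length (default 1024)
#' @return a `spectrum`: list with `freqs` (Hz), `psd` (ms^2/Hz),
#'   `n_epochs`, `window`, `nfft`
#' @export
welch_psd <- function(tach, nperseg = 256, noverlap = 128, nfft = 1024) {
  stopifnot(inherits(tach, "tachogram"))
  v <- tach$resampled
  fs <- tach$fs
  if (length(v) < nperseg)
    stop("tachogram too short for Welch epoching: need ", nperseg,
         " samples, got ", length(v))
  step <- nperseg - noverlap
  n_epochs <- floor((length(v) - nperseg) / step) + 1
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nperseg) - 1) / (nperseg - 1)))
  U <- sum(w^2)
  acc <- numeric(nfft / 2 + 1)
  for (e in seq_len(n_epochs)) {
    seg <- v[((e - 1) * step + 1):((e - 1) * step + nperseg)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, numeric(nfft - nperseg)))
    P <- Mod(X[seq_len(nfft / 2 + 1)])^2 / (fs * U)
    P[2:(nfft / 2)] <- 2 * P[2:(nfft / 2)]   # one-sided
    acc <- acc + P
  }
  structure(list(freqs = (0:(nfft / 2)) * fs / nfft,
                 psd = acc / n_epochs,
                 n_epochs = n_epochs, window = "hanning", nfft = nfft),
            class = "spectrum")
}

#' Integrate a spectrum into VLF/LF/HF band powers and log indices
#'
#' Rectangle-rule integration over the half-open bands of [hrv_bands()]
#' (bin-center membership). Powers are in ms^2; `ln_*` are natural logs and
#' `R = ln_lf - ln_hf` is the sympathovagal balance index. A zero band
#' power makes the corresponding log index `-Inf` with a warning.
#'
#' @param spec a [welch_psd()] result
#' @return a `spectral_indices`: list with `vlf`, `lf`, `hf`, `ln_vlf`,
#'   `ln_lf`, `ln_hf`, `ratio`
#' @export
band_powers <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  df <- spec$freqs[2] - spec$freqs[1]
  bands <- hrv_bands()
  pw <- vapply(bands, function(b) {
    sum(spec$psd[spec$freqs >= b[1] & spec$freqs < b[2]]) * df
  }, numeric(1))
  if (any(pw == 0)) warning("zero band power: log index undefined (-Inf)")
  structure(list(vlf = pw[["vlf"]], lf = pw[["lf"]], hf = pw[["hf"]],
                 ln_vlf = log(pw[["vlf"]]), ln_lf = log(pw[["lf"]]),
                 ln_hf = log(pw[["hf"]]),
                 ratio = log(pw[["lf"]]) - log(pw[["hf"]])),
            class = "spectral_indices")
}

#' Full spectral-index pipeline for one beat series
#'
#' Convenience chain: tachogram, Welch PSD, band powers.
#'
#' @param beats a `beat_series`
#' @param duration segment length in seconds
#' @return a `spectral_indices`
#' @export
beats_to_indices <- function(beats, duration) {
  band_powers(welch_psd(beats_to_tachogram(beats, duration)))
}
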