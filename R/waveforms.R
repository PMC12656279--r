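#' Synthesize a reference ECG from known beat times
#'
#' Places a single-Gaussian R-wave template (narrow positive deflection,
#' default width ~20 ms) at each beat time, evaluating the continuous-time
#' template at the sample instants of the requested rate. Amplitude is
#' normalized to 1. The shape is intentionally minimal: it only needs to
#' support unambiguous R-peak detection, not morphology research.
#'
#' @param beat_times beat times in seconds (may be empty)
#' @param fs sampling rate in Hz (>= 250)
#' @param duration signal length in seconds
#' @param width full width of the R wave in seconds (Gaussian sd = width/2.355)
#' @return an [hrv_signal()] at `fs`
#' @export
synthesize_ecg <- function(beat_times, fs, duration, width = 0.02) {
  stopifnot(fs >= 250, duration > 0, width > 0)
  n <- round(duration * fs)
  x <- numeric(n)
  if (length(beat_times) == 0) return(hrv_signal(x, fs))
  if (any(beat_times < 0) || any(beat_times > duration))
    stop("beat time outside signal span [0, duration]")
  sd <- width / 2.355                    # FWHM -> Gaussian sd
  half <- ceiling(5 * sd * fs)
  tgrid <- (seq_len(n) - 1) / fs
  for (bt in beat_times) {
    c0 <- round(bt * fs) + 1
    i <- max(1, c0 - half):min(n, c0 + half)
    x[i] <- x[i] + exp(-0.5 * ((tgrid[i] - bt) / sd)^2)
  }
  if (max(x) > 0) x <- x / max(x)
  hrv_signal(x, fs)
}

# Continuous-time PPG pulse template relative to its onset: a two-Gaussian
# shape (systolic peak + smaller, later dicrotic bump) whose superposition
# gives a fast rise and slow decay. Waveform maximum sits at t_sys.
ppg_pulse <- function(tau, t_sys = 0.15, sd_sys = 0.045,
                      t_dic = 0.34, a_dic = 0.2, sd_dic = 0.08) {
  exp(-0.5 * ((tau - t_sys) / sd_sys)^2) +
    a_dic * exp(-0.5 * ((tau - t_dic) / sd_dic)^2)
}

#' Synthesize a PPG from known beat times
#'
#' Each beat contributes one smooth asymmetric pulse whose onset is
#' `beat + ptt_mean + jitter`. Pulse transit time (PTT) jitter is Gaussian,
#' truncated at +/- 3 sd to preserve beat ordering, and seed-reproducible;
#' it is the generator's model of pulse-rate-variability vs HRV discrepancy.
#' Signals are synthesized directly at the target rate by evaluating the
#' continuous-time template at sample instants (native-rate digitization,
#' not decimation of a master recording).
#'
#' @param beat_times beat times in seconds
#' @param fs sampling rate in Hz (250, 500 and 1000 are the study rates)
#' @param duration signal length in seconds
#' @param ptt_mean mean pulse transit time in ms (>= 0, default 250)
#' @param ptt_jitter_sd per-beat PTT jitter sd in ms (0 = deterministic)
#' @param seed integer seed for the jitter draws
#' @return an [hrv_signal()] at `fs`
#' @export
synthesize_ppg <- function(beat_times, fs, duration,
                           ptt_mean = 250, ptt_jitter_sd = 0, seed = 1) {
  stopifnot(fs > 0, duration > 0, ptt_mean >= 0, ptt_jitter_sd >= 0)
  n <- round(duration * fs)
  x <- numeric(n)
  if (length(beat_times) == 0) return(hrv_signal(x, fs))
  if (length(beat_times) > 1 && any(diff(beat_times) < 0.3))
    stop("beat intervals below 300 ms would overlap pulse templates")
  jit <- if (ptt_jitter_sd > 0) {
    with_seed(seed, {
      j <- stats::rnorm(length(beat_times), 0, ptt_jitter_sd)
      pmax(pmin(j, 3 * ptt_jitter_sd), -3 * ptt_jitter_sd)
    })
  } else numeric(length(beat_times))
  onsets <- beat_times + (ptt_mean + jit) / 1000
  tgrid <- (seq_len(n) - 1) / fs
  half <- ceiling(0.8 * fs)              # template support ~0.8 s past onset
  for (k in seq_along(onsets)) {
    c0 <- round(onsets[k] * fs) + 1
    i <- max(1, c0 - ceiling(0.25 * fs)):min(n, c0 + half)
    if (length(i) == 0 || i[1] > n) next
    x[i] <- x[i] + ppg_pulse(tgrid[i] - onsets[k])
  }
  hrv_signal(x, fs)
}
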