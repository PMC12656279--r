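#' Configuration for a synthetic paired PPG-ECG cohort
#'
#' Describes the acquisition the generator emulates: `n_subjects` subjects
#' each contributing `n_segments` independent 2.5 min segments, with the
#' ECG reference at 1000 Hz and the PPG digitized natively at each rate in
#' `fs_list`. Subject-level physiology (mean RR and spectral component
#' amplitudes) is drawn once per subject from uniform ranges; segments
#' re-draw phases and jitter. Defaults give 10 x 3 = 30 paired
#' observations per PPG rate.
#'
#' @param n_subjects number of subjects (>= 1)
#' @param n_segments segments per subject (>= 1)
#' @param fs_list PPG sampling rates, a subset of 250/500/1000 Hz
#' @param duration segment length in seconds (150 = 2.5 min)
#' @param ptt_mean mean pulse transit time in ms
#' @param ptt_jitter_sd per-beat PTT jitter sd in ms
#' @param noise a [noise_spec()] applied to the PPG channel (the shielded
#'   ECG reference receives no added noise)
#' @param mean_rr_range,vlf_amp_range,lf_amp_range,hf_amp_range uniform
#'   ranges (ms) for subject-level RR mean and component amplitudes
#' @param vlf_freq,lf_freq,hf_freq component center frequencies (Hz)
#' @param seed master integer seed
#' @return a `cohort_config`
#' @export
cohort_config <- function(n_subjects = 10, n_segments = 3,
                          fs_list = c(250, 500, 1000), duration = 150,
                          ptt_mean = 250, ptt_jitter_sd = 0,
                          noise = noise_spec(),
                          mean_rr_range = c(750, 1050),
                          vlf_amp_range = c(15, 30),
                          lf_amp_range = c(25, 40),
                          hf_amp_range = c(20, 35),
                          vlf_freq = 0.015, lf_freq = 0.1, hf_freq = 0.25,
                          seed = 1) {
  stopifnot(n_subjects >= 1, n_segments >= 1, duration > 0,
            inherits(noise, "noise_spec"))
  if (!all(fs_list %in% c(250, 500, 1000)))
    stop("fs_list must be a subset of 250, 500, 1000 Hz")
  structure(list(n_subjects = n_subjects, n_segments = n_segments,
                 fs_list = fs_list, duration = duration,
                 ptt_mean = ptt_mean, ptt_jitter_sd = ptt_jitter_sd,
                 noise = noise,
                 mean_rr_range = mean_rr_range,
                 vlf_amp_range = vlf_amp_range,
                 lf_amp_range = lf_amp_range,
                 hf_amp_range = hf_amp_range,
                 vlf_freq = vlf_freq, lf_freq = lf_freq, hf_freq = hf_freq,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic paired cohort
#'
#' For each (subject, segment): one RR realization (shared across all PPG
#' rates — the paired design), a 1000 Hz ECG reference, and a PPG per rate
#' in `fs_list` with PTT jitter and the configured noise. Hierarchical
#' seeding (subject-level draws from the subject seed, segment-level from
#' the segment seed) makes the cohort a pure function of the config.
#'
#' @param config a [cohort_config()]
#' @return list of `paired_recording` objects (one per subject x segment),
#'   each with fields `ecg` (1000 Hz [hrv_signal()]), `ppg` (named list of
#'   [hrv_signal()] by rate), `true_beat_times`, `subject_id`,
#'   `segment_id`, `rr_spec`
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  recs <- list()
  for (subj in seq_len(config$n_subjects)) {
    pars <- with_seed(derive_seed(config$seed, 9000, subj), {
      list(mean_rr = stats::runif(1, config$mean_rr_range[1], config$mean_rr_range[2]),
           vlf_amp = stats::runif(1, config$vlf_amp_range[1], config$vlf_amp_range[2]),
           lf_amp  = stats::runif(1, config$lf_amp_range[1], config$lf_amp_range[2]),
           hf_amp  = stats::runif(1, config$hf_amp_range[1], config$hf_amp_range[2]))
    })
    for (seg in seq_len(config$n_segments)) {
      seg_seed <- derive_seed(config$seed, subj, seg)
      spec <- rr_process_spec(
        mean_rr = pars$mean_rr,
        components = list(
          list(freq = config$vlf_freq, amplitude = pars$vlf_amp, kind = "sinusoid"),
          list(freq = config$lf_freq, amplitude = pars$lf_amp, kind = "sinusoid"),
          list(freq = config$hf_freq, amplitude = pars$hf_amp, kind = "sinusoid")),
        duration = config$duration, seed = seg_seed)
      beats <- generate_rr_series(spec)
      beats <- beats[beats <= config$duration - 1]   # leave room for the pulse
      ecg <- synthesize_ecg(beats, fs = 1000, duration = config$duration)
      ppg <- list()
      for (fs in config$fs_list) {
        p <- synthesize_ppg(beats, fs = fs, duration = config$duration,
                            ptt_mean = config$ptt_mean,
                            ptt_jitter_sd = config$ptt_jitter_sd,
                            seed = derive_seed(seg_seed, 77))
        np <- config$noise
        np$seed <- derive_seed(seg_seed, 88)
        ppg[[as.character(fs)]] <- add_noise(p, np)
      }
      recs[[length(recs) + 1]] <- structure(
        list(ecg = ecg, ppg = ppg, true_beat_times = beats,
             ptt_mean = config$ptt_mean,
             ptt_jitter_sd = config$ptt_jitter_sd,
             subject_id = subj, segment_id = seg, rr_spec = spec),
        class = "paired_recording")
    }
  }
  recs
}

#' @export
print.paired_recording <- function(x, ...) {
  cat(sprintf("<paired_recording> subject %d segment %d: %d beats, PPG @ %s Hz\n",
              x$subject_id, x$segment_id, length(x$true_beat_times),
              paste(names(x$ppg), collapse = "/")))
  invisible(x)
}
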