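test_that("constant-rate IPFM emits exactly periodic beats", {
  beats <- generate_rr_series(rr_process_spec(mean_rr = 1000, duration = 150))
  expect_length(beats, 151)           # beat at 0 plus 150 intervals
  expect_equal(diff(beats), rep(1, 150), tolerance = 1e-9)

  beats2 <- generate_rr_series(rr_process_spec(mean_rr = 800, duration = 80))
  expect_equal(diff(beats2), rep(0.8, length(beats2) - 1), tolerance = 1e-8)
})

test_that("single-tone modulation dominates the tachogram spectrum at its frequency", {
  spec <- rr_process_spec(1000, list(list(freq = 0.25, amplitude = 30,
                                          kind = "sinusoid")),
                          duration = 150, seed = 3)
  beats <- generate_rr_series(spec)
  sp <- welch_psd(beats_to_tachogram(beats_from_times(beats), 150))
  peak_f <- sp$freqs[which.max(sp$psd)]
  expect_lt(abs(peak_f - 0.25), sp$freqs[2] - sp$freqs[1] + 1e-12)
})

test_that("modulation below the 300 ms floor is rejected", {
  spec <- rr_process_spec(400, list(list(freq = 0.1, amplitude = 150,
                                         kind = "sinusoid")),
                          duration = 60, seed = 1)
  expect_error(generate_rr_series(spec), "300 ms")
})

test_that("beat generation is a pure function of (spec, seed)", {
  spec <- rr_process_spec(900, list(list(freq = 0.1, amplitude = 25, kind = "sinusoid"),
                                    list(freq = 0.3, amplitude = 20,
                                         kind = "band-limited-noise")),
                          duration = 120, seed = 42)
  b1 <- generate_rr_series(spec)
  b2 <- generate_rr_series(spec)
  expect_identical(b1, b2)
  spec$seed <- 43L
  expect_false(identical(b1, generate_rr_series(spec)))
})

test_that("two-tone spec recovers sinc-corrected analytic band powers end to end", {
  spec <- rr_process_spec(1000, list(list(freq = 0.1, amplitude = 30, kind = "sinusoid"),
                                     list(freq = 0.25, amplitude = 30, kind = "sinusoid")),
                          duration = 150, seed = 4)
  beats <- generate_rr_series(spec)
  idx <- beats_to_indices(beats_from_times(beats), 150)
  truth <- analytic_band_powers(spec)
  expect_lt(abs(idx$lf - truth[["lf"]]) / truth[["lf"]], 0.10)
  expect_lt(abs(idx$hf - truth[["hf"]]) / truth[["hf"]], 0.10)
})

test_that("ECG synthesis centers one R template per beat", {
  x <- synthesize_ecg(c(1, 2, 3), fs = 1000, duration = 4)
  expect_equal(length(x$samples), 4000)
  expect_equal(max(x$samples), 1)
  for (b in c(1, 2, 3)) {
    win <- (b * 1000 - 250):(b * 1000 + 250)
    expect_lte(abs(win[which.max(x$samples[win])] - (b * 1000 + 1)), 1)
  }
  expect_equal(synthesize_ecg(numeric(0), 1000, 2)$samples, numeric(2000))
  expect_error(synthesize_ecg(5, 1000, 4), "span")
})

test_that("ECG peak times agree across sampling rates", {
  beats <- c(0.5, 1.4, 2.5, 3.3)
  for (b in beats) {
    t500 <- with(synthesize_ecg(beats, 500, 4), (which.max(
      samples * (abs((seq_along(samples) - 1) / 500 - b) < 0.2)) - 1) / 500)
    t1000 <- with(synthesize_ecg(beats, 1000, 4), (which.max(
      samples * (abs((seq_along(samples) - 1) / 1000 - b) < 0.2)) - 1) / 1000)
    expect_lte(abs(t500 - t1000), 1 / 500)
  }
})

test_that("PPG pulse peaks sit at beat + PTT and intervals difference out the delay", {
  x <- synthesize_ppg(c(1, 2), fs = 1000, duration = 4, ptt_mean = 250)
  t <- (seq_along(x$samples) - 1) / 1000
  p1 <- t[which.max(x$samples * (t < 1.8))]
  expect_lt(abs(p1 - 1.40), 0.02)      # onset 1.25 + systolic rise
  beats <- seq(0.5, 140, by = 0.9)
  pp <- detect_ppg_peaks(apply_zero_phase(
    design_study_filter("butterworth", 1000),
    synthesize_ppg(beats, 1000, 150, ptt_mean = 250, ptt_jitter_sd = 0)))
  ints <- pp$intervals
  expect_lt(max(abs(ints - 900)), 1000 / 1000 + 1e-9)   # within one sample
})

test_that("PTT jitter propagates to detected intervals with sqrt(2) inflation", {
  spec <- rr_process_spec(850, duration = 500)
  beats <- generate_rr_series(spec)
  beats <- beats[beats <= 499]
  x <- synthesize_ppg(beats, fs = 1000, duration = 500, ptt_mean = 250,
                      ptt_jitter_sd = 10, seed = 9)
  pp <- detect_ppg_peaks(apply_zero_phase(design_study_filter("butterworth", 1000), x))
  expect_equal(length(pp$peak_times), length(beats))
  err <- pp$intervals - diff(beats) * 1000
  expect_gt(length(err), 500)
  expect_lt(abs(sd(err) - sqrt(2) * 10) / (sqrt(2) * 10), 0.20)
})

test_that("noise is additive, seed-stable and exactly absent at zero amplitude", {
  x <- synthesize_ppg(seq(0.5, 9.5, by = 1), fs = 250, duration = 10)
  expect_identical(add_noise(x, noise_spec(seed = 5))$samples, x$samples)
  n1 <- noise_spec(baseline_wander = c(0.2, 0.5), seed = 7)
  n2 <- noise_spec(white_sd = 0.1, seed = 7)
  n12 <- noise_spec(baseline_wander = c(0.2, 0.5), white_sd = 0.1, seed = 7)
  expect_equal(add_noise(add_noise(x, n1), n2)$samples,
               add_noise(x, n12)$samples, tolerance = 1e-12)
  expect_identical(add_noise(x, n12)$samples, add_noise(x, n12)$samples)
})

test_that("powerline contamination carries the analytic tone power", {
  x <- hrv_signal(numeric(20000), fs = 1000)
  a <- 0.7
  y <- add_noise(x, noise_spec(powerline = c(60, a), seed = 3))
  # tone power via the periodogram bin at 60 Hz (exact bin: 20000/1000*60)
  X <- fft(y$samples)
  p60 <- 2 * Mod(X[60 * 20 + 1])^2 / length(y$samples)^2
  expect_lt(abs(p60 - a^2 / 2) / (a^2 / 2), 0.05)
})

test_that("wander is attenuated at least as much as the filter response predicts", {
  x <- hrv_signal(numeric(60000), fs = 1000)
  y <- add_noise(x, noise_spec(baseline_wander = c(0.2, 1), seed = 11))
  cf <- design_study_filter("butterworth", 1000)
  filt <- apply_zero_phase(cf, y)
  # zero-phase gain at 0.2 Hz from the designed response
  w <- 2 * pi * 0.2 / 1000
  gain2 <- Mod(sum(cf$b * exp(-1i * w * (0:4))) / sum(cf$a * exp(-1i * w * (0:4))))^2
  mid <- 10000:50000
  att <- sd(filt$samples[mid]) / sd(y$samples[mid])
  expect_lte(att, gain2 * 1.05)
})

test_that("cohorts have the study geometry and are byte-identical under a fixed seed", {
  cfg <- cohort_config(n_subjects = 2, n_segments = 2, fs_list = c(250, 500),
                       duration = 60, seed = 21)
  recs <- generate_cohort(cfg)
  expect_length(recs, 4)
  expect_named(recs[[1]]$ppg, c("250", "500"))
  expect_equal(signal_duration(recs[[1]]$ecg), 60)
  expect_equal(signal_duration(recs[[1]]$ppg[["250"]]), 60)
  expect_true(all(diff(recs[[1]]$true_beat_times) >= 0.3))
  expect_identical(serialize(generate_cohort(cfg), NULL),
                   serialize(generate_cohort(cfg), NULL))
  one <- generate_cohort(cohort_config(n_subjects = 1, n_segments = 1,
                                       fs_list = 250, seed = 3))
  expect_length(one, 1)
  expect_equal(signal_duration(one[[1]]$ecg), 150)
})
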