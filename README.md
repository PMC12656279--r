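# ppghrv

Validating IIR bandpass preprocessing for PPG-derived heart rate
variability against a simultaneous ECG reference.

Wearable devices estimate heart rate variability (HRV) from
photoplethysmography (PPG) pulse intervals instead of ECG RR intervals.
Whether the two are interchangeable depends on the preprocessing chain:
the bandpass filter (its family, ripple and phase behavior) and the
sampling rate jointly distort pulse timing and hence the spectral HRV
indices. `ppghrv` implements a complete benchmark of that question for
the two standard IIR candidates — Butterworth (maximally flat) and
elliptic (equiripple, sharpest transition) — at 1000, 500 and 250 Hz,
applied zero-phase (forward–backward, squaring the magnitude response
and cancelling the phase).

The package provides, as tested building blocks:

* **Filter design and application** — prewarped bilinear designs
  reproducing the study's published coefficient tables
  (`design_study_filter()`, `load_reference_coefficients()`), the
  direct-form recursion (`apply_filter()`), zero-phase filtering with a
  fixed odd-reflection padding rule (`apply_zero_phase()`), notch and ECG
  preprocessing chains.
* **Filter characterization** — frequency response, analytic group delay,
  pole–zero geometry with stability verdicts, passband ripple/transition
  widths, and a spectral-fidelity score of the zero-phase response
  against the ideal 0.8–20 Hz brick wall
  (`frequency_response()`, `group_delay()`, `pole_zero()`,
  `band_metrics()`, `spectral_fidelity()`).
* **HRV extraction** — Pan–Tompkins R-peak detection, adaptive PPG pulse
  detection with a 300 ms physiological floor, 4 Hz cubic-spline
  tachogram, Welch spectra (256/128/Hann/1024), VLF/LF/HF band powers,
  their natural logs and `R = ln(LF/HF)`
  (`detect_ecg_rpeaks()`, `detect_ppg_peaks()`, `beats_to_tachogram()`,
  `welch_psd()`, `band_powers()`).
* **Agreement statistics** — Lin's concordance correlation coefficient
  `CCC = 2·cov(x,y) / (σ²x + σ²y + (μx − μy)²)` with bootstrap CI and the
  `CCC = r × Cb` decomposition; paired TOST equivalence against ±0.05
  ln-unit bounds with Holm correction; Passing–Bablok regression;
  Bland–Altman limits of agreement
  (`ccc()`, `tost()`, `holm_adjust()`, `passing_bablok()`,
  `bland_altman()`, `build_report()`).
* **A synthetic paired-cohort generator** — integral pulse frequency
  modulation RR processes with analytically known band powers, template
  ECG/PPG waveforms digitized natively at each rate, pulse-transit-time
  jitter, and composable noise (wander, powerline, white, motion bursts),
  all deterministic under a seed
  (`rr_process_spec()`, `generate_cohort()`, `study_cohort()`).

The numbered scripts under `analysis/` run the study end to end and
write their tables under `results/`; the methods vignette
(`vignettes/filter-validation-methods.Rmd`) documents the model,
parameter choices, and the provenance analysis of the published
coefficient tables (including the print artifacts found there).

## Worked example

Design the 500 Hz Butterworth bandpass the study deployed and check it
against the published table:

```r
library(ppghrv)
cf <- design_study_filter("butterworth", 500)
round(cf$b, 8)
#> [1]  0.00308602  0.00000000 -0.00617203  0.00000000  0.00308602
round(cf$a, 8)
#> [1]  1.00000000 -3.83439868  5.51815832 -3.53292690  0.84916874
pole_zero(cf)$stable
#> [1] TRUE
```

These match the published coefficients digit for digit except `a1`
(printed −3.83439915), which no double-precision design reproduces — one
of several print artifacts the package documents (see the vignette).

Run the clean-scenario benchmark (10 subjects × 3 segments × 6
configurations, no noise, zero jitter):

```r
res <- run_experiment(experiment_config(study_cohort("clean", seed = 20260925)))
min(res$agreement$ccc)
#> [1] 0.9995414
all(res$agreement$equivalent)
#> [1] TRUE
```

Every configuration tracks the ECG reference nearly perfectly on clean
signals — the ground-truth closure that validates the pipeline. Under
the ambulatory stress preset (`study_cohort("ambulatory", ...)`,
adding wander, 60 Hz pickup, broadband noise, motion bursts and 5 ms
pulse-transit jitter), concordance at 250 Hz drops into the 0.8–0.9
range for ln HF with Butterworth consistently above elliptic
(`analysis/04_ambulatory_benchmark.R` prints, for five replicate
cohorts, e.g. 0.893 vs 0.850), reproducing the qualitative pattern that
motivates Butterworth ≥ 500 Hz as the recommended configuration.

Spectral fidelity of the zero-phase responses against the ideal 0.8–20 Hz
bandpass (raw, and normalized to Butterworth 1000 Hz = 100):

```r
res$fidelity
#>        filter   fs   sf_raw sf_normalized
#> 1 butterworth  250 62.04876      68.85409
#> 2 butterworth  500 62.22370      69.04822
#> 3 butterworth 1000 90.11630     100.00000
#> 4    elliptic  250 68.92394      76.48333
#> 5    elliptic  500 69.14633      76.73010
#> 6    elliptic 1000 84.24644      93.48635
```

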