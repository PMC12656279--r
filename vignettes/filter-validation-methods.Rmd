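---
title: "Methods: validating IIR bandpass preprocessing for PPG-derived HRV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating IIR bandpass preprocessing for PPG-derived HRV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppghrv)
```

## The problem

Heart rate variability (HRV) is conventionally measured from the RR
intervals of an ECG. Wearable devices instead use photoplethysmography
(PPG), whose pulse-peak intervals track RR intervals only as well as the
signal chain allows: the bandpass filter that removes baseline wander and
noise also distorts pulse timing, and lower sampling rates quantize peak
locations. `ppghrv` rebuilds a filter-validation study as a tested
pipeline: it designs and characterizes the candidate filters (Butterworth
and elliptic bandpass, nominally 0.8--20 Hz, applied zero-phase, at 1000,
500 and 250 Hz), extracts frequency-domain HRV indices from paired
PPG/ECG recordings, and quantifies PPG-vs-ECG interchangeability with
four complementary agreement methods. Because the original human
recordings are not deposited, the paired cohort is synthesized by a
generator whose ground truth is known analytically; every downstream
stage is therefore testable without any data download.

## Filter design and the provenance of the published coefficients

The filters are second-order-specification IIR bandpasses (degree-4
polynomials after the bandpass transformation), designed from the analog
prototype via the bilinear transform with prewarped band edges, and
normalized so the leading denominator coefficient is 1. Butterworth
designs use `signal::butter`; elliptic designs use `signal::ellip` with
1 dB passband ripple and a stopband attenuation of `ELLIPTIC_RS` = 80 dB,
recovered by a one-dimensional calibration against the published 1000 Hz
elliptic coefficients (a 20--80 dB grid search at 0.1 dB resolution; the
published set is reproduced to ~2e-8 at the optimum, pinning the value).

Reproducing the published coefficient sets required a forensic pass, and
three findings shape the package's conventions. All three are verifiable
with the package itself (`analysis/01_design_filters.R` prints the
comparisons).

1. **Effective band edges.** The published 1000 Hz columns follow from a
   standard 0.8--20 Hz design, but the 500 and 250 Hz columns only
   reproduce when the upper edge is normalized by the sampling rate
   rather than the Nyquist rate -- an effective upper edge of 10 Hz at
   those rates. `study_band_edges()` exposes this recovered convention,
   and `design_study_filter()` uses it so that designed and published
   filters coincide. The nominal 0.8--20 Hz design at any rate remains
   available through `filter_spec()` + `design_butterworth_bandpass()`.
2. **Print artifacts in the Butterworth table.** Two printed values are
   not reproducible by any double-precision design: the 500 Hz
   denominator's second coefficient (off by 4.7e-7; a least-squares
   search over all edge pairs bottoms out at 3.1e-7, so no design matches
   it) and the 1000 Hz numerator's middle coefficient, which equals
   exactly -2x the *rounded* first coefficient rather than the correctly
   rounded design value (1e-8 off). The remaining 29 of 30 published
   Butterworth coefficients reproduce at printed precision. Tests assert
   digit-exact agreement where the print is self-consistent and pin the
   two artifacts at their measured bounds.
3. **Errata in the elliptic table.** As printed, the elliptic numerators
   give the filter a DC gain of ~3e4 -- impossible for a bandpass whose
   zeros lie on the unit circle -- and negating the middle numerator
   coefficient makes the 1000 Hz column match the rp = 1 dB, rs = 80 dB
   design to 2e-8. The shipped fixtures carry that sign correction.
   The 500 and 250 Hz elliptic columns are more deeply corrupted: no
   elliptic design (free ripple, attenuation and both edges) comes
   within ~1e-3 of them, and their printed denominators have pole moduli
   of 1.13 and 1.17 -- unstable as printed, contradicting the source's
   own stability statement. The pipeline therefore always runs on
   *designed* elliptic filters (all stable); the printed sets are kept
   verbatim (plus the sign erratum) as `load_reference_coefficients()`
   fixtures, and the instability of the two corrupted columns is itself
   asserted in the test suite as documentation.

A note on the elliptic design library: the installed designer's Cauer
approximation differs from the reference stack's at the ~3e-5 coefficient
level, which bounds how closely a designed elliptic filter can track even
the reproducible 1000 Hz fixture. Tests assert the agreement at that
library-precision bound (1e-4 per coefficient).

## Zero-phase filtering

Causal IIR filtering delays each frequency by its group delay, biasing
beat timing. The pipeline therefore applies every bandpass forward and
backward (`apply_zero_phase()`): the effective magnitude response is the
squared single-pass response and the net phase is identically zero, which
doubles the effective order without latency. Edge transients are handled
by odd-reflection padding of length 3 x (filter length - 1) at both ends,
discarded after the backward pass; the rule is fixed (rather than
delegated to a library default) so results are bit-reproducible. Inputs
must be longer than three filter lengths; shorter inputs raise an error
naming the minimum.

The squared-gain and zero-phase contracts are verified empirically: the
transfer function measured from a filtered centered impulse equals the
squared single-pass gain to 1e-6 relative on a 1024-point grid, with
measured phase below 1e-6 rad wherever the response is resolvable.

## Filter characterization

`frequency_response()` evaluates the transfer function by direct
polynomial ratio on a linear grid; `group_delay()` computes the negative
phase derivative analytically from the coefficient polynomials (grid
points coinciding with exact response zeros are flagged);
`pole_zero()` factors both polynomials and reports a stability verdict.

`band_metrics()` reports passband ripple and transition widths. Ripple
is measured as the magnitude span between the outermost local gain maxima
inside the passband: a monotone (maximally flat) response reports 0 and an
equiripple response reports its design ripple. This definition replaces a
fixed interior window (e.g. 10--90% of the passband), which would charge
the Butterworth's own edge roll-off (~2 dB over so wide a window) to
"ripple" and make the flat-vs-equiripple distinction meaningless.
Transition widths run from the -3 dB edge to the first crossing of a
parametric attenuation (default 20 dB, since the level defining the
published widths is unstated); published width and group-delay-spread
figures are therefore reproduced qualitatively, not asserted numerically.

`spectral_fidelity()` scores the zero-phase (squared) magnitude against a
brick-wall ideal with unity gain in 0.8--20 Hz and zero outside:
`SF = (1 - sum((H_ideal - H_actual)^2) / sum(H_ideal^2)) x 100`, on a
linear grid of K = 4096 points from 0 to Nyquist (the source states
neither K nor spacing; 4096 is converged -- doubling K moves SF by less
than 0.1 points). Raw scores and scores normalized to the Butterworth
1000 Hz reference are both reported. On the shipped fixtures the raw
scores order Butterworth above elliptic at every rate and 1000 Hz above
the sub-kHz designs; the one published ordering that does *not* follow
from this definition is 500-above-250 Hz Butterworth, where the two
scores sit 0.17 points apart in the wrong order -- an artifact of the
corrupted 500 Hz print (the cleanly designed 500 Hz filter does score
above 250 Hz). The corresponding acceptance expectation is left failing
rather than redefined around the defect.

## The synthetic cohort generator

The generator emulates the study's acquisition: 10 subjects x 3
independent 2.5-min segments, ECG reference at 1000 Hz, PPG digitized
natively at 250/500/1000 Hz, 30 paired observations per configuration.

**RR process.** Beat times come from integral pulse frequency modulation
(`generate_rr_series()`): the instantaneous rate 1/RR(t) is integrated
and a beat fires at each integer crossing. RR(t) is a mean plus spectral
components (sinusoids or band-limited noise) in the VLF/LF/HF bands. For
sinusoidal components the tachogram band powers are known in closed form,
with one physical subtlety: a measured beat interval averages the
modulation over the beat, attenuating a component at frequency f by
sinc(pi f T) in amplitude (T = mean RR). `analytic_band_powers()` applies
the sinc^2 factor by default, and the end-to-end recovery tests assert
agreement with this corrected truth within 10%. Specs whose modulation
would drive RR below the 300 ms physiological floor are rejected.

**Waveforms.** The ECG R wave is a single Gaussian (~20 ms width,
amplitude 1); the PPG pulse is a two-Gaussian shape (systolic peak at
+0.15 s, dicrotic bump at +0.34 s at 0.2 amplitude) giving a fast rise
and slow decay. The dicrotic latency is deliberately inside the 300 ms
refractory window of the systolic peak so it can never be double-counted
as a beat. Shapes are evaluated in continuous time at each target rate's
sample instants -- native-rate digitization, not decimation. Pulse onset
lags each beat by the pulse transit time (default mean 250 ms); per-beat
Gaussian PTT jitter (truncated at +-3 sd) models pulse-rate-vs-HRV
discrepancy, and detected-interval noise inflates by sqrt(2) relative to
the per-beat jitter, which the tests verify.

**Noise.** `noise_spec()` adds baseline wander, 60 Hz powerline pickup,
white sensor noise and Hann-windowed low-frequency motion bursts, each
drawing from its own derived seed so components are independent and
sequential application equals joint application, exactly. Zero amplitudes
are bit-exact pass-throughs. Subject heterogeneity draws mean RR
(750--1050 ms) and component amplitudes (VLF 15--30, LF 25--40, HF 20--35
ms at 0.015/0.1/0.25 Hz) once per subject; one RR realization per
(subject, segment) is shared across all PPG rates, mirroring a paired
design. Everything is a pure function of (config, seed); two runs with
the same seed serialize identically.

**Noise scenarios.** The source reports no SNR for its recordings, so the
two named presets are this package's own calibration. `"clean"` is
noise-free with zero jitter and is the ground-truth closure condition:
every configuration must track the ECG reference nearly perfectly
(CCC > 0.99, equivalence everywhere), which isolates pipeline error from
scenario difficulty. `"ambulatory"` (wander 0.3 at 0.25 Hz, powerline
0.15, white sd 0.2, one 1-s motion burst per minute at 0.2, plus 5 ms PTT
jitter; pulse amplitude is ~1) was chosen to reproduce the *qualitative*
degradation ordering reported for noisy low-rate conditions -- moderate
concordance at 250 Hz with Butterworth above elliptic -- and is asserted
only directionally, never as the study's SNR. The mechanism that
separates the families is physical rather than tuned: relative to the
monotone Butterworth, the equiripple elliptic passes 1.3--2x more noise
power near both passband edges, and peak-timing error weights the upper
edge heavily, so broadband noise inflates elliptic HF timing noise more.

## HRV extraction

ECG R-peaks use the classic five-stage cascade (`detect_ecg_rpeaks()`):
5--15 Hz bandpass emphasis, five-point derivative, squaring, 150 ms
moving-window integration, and adaptive signal/noise thresholds with the
original 200 ms lockout; detections map back to the maximum of the
(zero-phase preprocessed) waveform, and the study's 300 ms floor is
enforced on the final interval series. The reference channel is always
processed at 1000 Hz after a 0.5--40 Hz zero-phase Butterworth and 60 Hz
notch (`preprocess_ecg()`).

PPG peaks (`detect_ppg_peaks()`) are local maxima above an adaptive
threshold -- 0.4x a reference amplitude taken as the median of the
tallest maxima, counting only as many as a 43 bpm heart rate could
produce so that noise bumps cannot drag the reference down -- with the
300 ms refractory resolving conflicts in favor of the taller peak, and
parabolic sub-sample refinement so behavior is rate-independent. The
waveform maximum is the fiducial, matching the peak-detection convention
of the source.

Intervals become a tachogram (`beats_to_tachogram()`): knots at beat
times valued by the interval ending there, natural cubic spline, uniform
4 Hz resampling over the segment (600 samples per 2.5 min). Welch
spectra (`welch_psd()`) use 256-sample epochs with 50% overlap -- three
full epochs per segment, the 88 trailing samples discarded (partial-epoch
handling is unstated in the source) -- per-epoch mean removal (without
which the RR mean's DC leakage would swamp VLF and make its log
meaningless), Hann window with power normalization, 1024-point FFT,
one-sided averaging. Band powers integrate the PSD by rectangle rule
over half-open bands [lo, hi) by bin center -- VLF 0.0033--0.04, LF
0.04--0.15, HF 0.15--0.40 Hz -- so boundary bins are never counted twice;
powers are in ms^2, logs are natural, and `R = ln LF - ln HF` exactly.

Two caveats are inherited deliberately: VLF over 2.5 min is below the
band's resolvable period (implemented as specified; physiological
validity not asserted), and the 4 Hz/1024-point grid gives 3.9 mHz bins,
so VLF holds only ~9 bins.

## Agreement statistics

All four methods operate on the 30 paired (subject, segment)
observations per configuration, differences oriented PPG - ECG.

* **Lin's CCC** (`ccc()`): plug-in moments,
  `2 cov / (var_x + var_y + (mean_x - mean_y)^2)`; Pearson's r and the
  bias-correction factor Cb = CCC / r are reported, and CCC = r x Cb is
  an exact identity of the implementation. CIs are percentile bootstrap
  over paired resampling (B = 2000 by default, seeded; the source states
  "bootstrap" without variant or B).
* **TOST** (`tost()`): paired t-based two one-sided tests against
  +-0.05 ln-unit bounds (the source's "+-5%" phrasing is the same
  quantity, since a log difference approximates relative change);
  equivalence iff both one-sided p < 0.05, identical to the 90% CI lying
  inside the bounds -- the duality is property-tested on random data, and
  the test's size at the equivalence boundary is verified at ~5%.
  Zero-variance differences degenerate to exact point comparison.
* **Holm** (`holm_adjust()`): step-down adjustment via `stats::p.adjust`,
  cross-checked against a direct enumeration oracle; the family is all
  band x configuration tests in the invoked report (18 in the full
  design). The source states the correction but not the family.
* **Passing--Bablok** (`passing_bablok()`): shifted median of all
  pairwise slopes (equal-x pairs skipped, slopes of exactly -1 excluded,
  offset K = count of slopes below -1), rank-based CIs; verified against
  brute-force enumeration.
* **Bland--Altman** (`bland_altman()`): bias, SD of differences (n-1) and
  bias +- 1.96 SD limits, with 95% coverage property-tested.

`build_report()` joins the PPG and ECG index tables on (subject,
segment) -- unmatched keys are an error naming them -- and emits one row
per band x filter x rate with all four methods' summaries and
Holm-adjusted equivalence verdicts. Row order of the inputs is
irrelevant to the output.

The source pools the 3 segments per subject as 30 independent pairs; the
package replicates that pooling. Within-subject correlation is therefore
ignored in both, which likely makes CIs somewhat anticonservative; a
mixed-model treatment is out of scope by design.

## Benchmark orchestration and problem sizes

`run_experiment()` ties the stages together: cohort generation, the ECG
reference path once per recording, the PPG path per configuration, the
agreement report, and the spectral-fidelity characterization, with any
stage failure identified by (subject, segment, configuration). The
`analysis/` scripts are thin narrative drivers over these functions and
write their tables under `results/`.

Problem sizes used by the shipped analyses and tests: the full cohort is
10 x 3 segments of 150 s (the study geometry); the clean-closure and
ambulatory benchmarks each run all 6 configurations on one cohort; the
directional Butterworth-vs-elliptic check runs 20 replicate cohorts at
250 Hz; statistical-engine verifications use 1000 random datasets for
the TOST duality, 5000 replicates for its boundary size, 50 enumeration
cross-checks each for Passing--Bablok (n = 10) and Holm, and n = 1e4 for
Bland--Altman coverage. A full clean-scenario experiment completes in
well under a minute on one CPU.

## Known limitations

* The generator's pulses are morphologically fixed per template; real PPG
  varies beat to beat with vasomotion and respiration, so passing the
  clean-closure tests demonstrates pipeline correctness, not robustness
  to morphology drift. The noise presets probe additive contamination
  only.
* No respiration, ectopy or arrhythmia is simulated, and no manual peak
  correction is modeled (the source inspected and corrected peaks
  manually; this package's detection runs fully automatic, so its noise
  tolerance is deliberately kept in the regime where detection is
  complete).
* The published elliptic 500/250 Hz coefficient sets are corrupted in
  print (see above); conclusions about those configurations rest on the
  calibrated re-designs, not on the printed values.
* Published Table-level group-delay spreads, transition widths and
  spectral-fidelity magnitudes are under-specified (evaluation bands,
  attenuation levels and grids unstated) and are reproduced only
  qualitatively or as orderings.
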