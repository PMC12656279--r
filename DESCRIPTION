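Package: ppghrv
Title: Filter-Sampling Validation of PPG-Derived Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks IIR bandpass preprocessing for photoplethysmography
    (PPG)-based heart rate variability (HRV) against a simultaneous ECG
    reference. Provides zero-phase Butterworth and elliptic bandpass design
    and characterization (frequency response, group delay, pole-zero
    geometry, spectral fidelity), frequency-domain HRV extraction (peak
    detection, 4 Hz cubic-spline tachogram, Welch spectra, VLF/LF/HF band
    powers), a four-method agreement framework (Lin's concordance
    correlation, TOST equivalence with Holm correction, Passing-Bablok
    regression, Bland-Altman limits of agreement), and a synthetic paired
    PPG-ECG cohort generator with known ground-truth spectral structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
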