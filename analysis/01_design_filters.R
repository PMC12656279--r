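#!/usr/bin/env Rscript
# Design the six study filters (Butterworth / elliptic x 1000 / 500 / 250 Hz)
# and compare them against the published coefficient sets.

suppressMessages(library(ppghrv))
dir.create("results", showWarnings = FALSE)

message("Designing 0.8-20 Hz bandpass filters (study edge convention) ...")
for (fam in c("butterworth", "elliptic")) {
  tab <- coefficients_table(fam, source = "designed")
  utils::write.csv(tab, file.path("results",
                                  paste0("coefficients_", fam, "_designed.csv")),
                   row.names = FALSE)
  fix <- coefficients_table(fam, source = "fixture")
  utils::write.csv(fix, file.path("results",
                                  paste0("coefficients_", fam, "_published.csv")),
                   row.names = FALSE)
  for (fs in c(1000, 500, 250)) {
    d <- design_study_filter(fam, fs)
    f <- load_reference_coefficients(fam, fs)
    message(sprintf("  %-11s %4d Hz: max |designed - published| = %.2e",
                    fam, fs, max(abs(c(d$b - f$b, d$a - f$a)))))
  }
}

message("\nEffective band edges recovered from the published designs:")
for (fs in c(1000, 500, 250)) {
  e <- study_band_edges(fs)
  message(sprintf("  %4d Hz: %.1f-%.1f Hz", fs, e[1], e[2]))
}
message("\nThe Butterworth sets reproduce to printed precision (up to two")
message("documented print artifacts at 500 Hz and in the 1000 Hz b2); the")
message("elliptic 1000 Hz set is reproduced by rp = 1 dB, rs = 80 dB after")
message("a sign correction on b2. See the methods vignette for the full")
message("provenance analysis. Tables written to results/.")
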