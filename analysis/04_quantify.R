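#!/usr/bin/env Rscript
# Stage 4 — quantification.
#
# Quantifies every sample and spike replicate three ways: the
# external-standard method (each analyte's own curve), slope-factor QAMS
# (intercept-corrected single-marker equations) and ratio-factor QAMS
# (intercept-free equations), using the in-sample marker peak as the
# fresh single-marker measurement.

suppressPackageStartupMessages(library(qamsvg))

peaks <- read_peak_table("results/peak_table.csv")
fits <- calibrate_peak_table(peaks)
markers <- list(PDA = vg_marker_assignment("PDA"),
                ELSD = vg_marker_assignment("ELSD"))
factors <- build_fx_table(fits, peaks, markers, days = 1:3,
                          provenance = "intra_day")

quant <- quantify_samples(peaks, fits, factors, markers,
                          volume_ml = 5, mass_mg = 100)
write.csv(quant, "results/quantification.csv", row.names = FALSE)

means <- aggregate(content_pct ~ compound + detector + method,
                   data = quant[quant$role == "sample", ], mean)
cat("mean contents (% dry weight) of the sample replicates:\n")
print(reshape(means, idvar = c("compound", "detector"),
              timevar = "method", direction = "wide"),
      row.names = FALSE, digits = 3)
flagged <- unique(quant[quant$out_of_range,
                        c("compound", "detector", "role")])
if (nrow(flagged)) {
  cat("concentrations outside the calibrated range (flagged, kept):\n")
  print(flagged, row.names = FALSE)
}
cat("wrote results/quantification.csv\n")
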