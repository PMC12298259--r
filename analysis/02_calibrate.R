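#!/usr/bin/env Rscript
# Stage 2 — fit detector response curves.
#
# Linear fits (area vs mg/mL) for PDA, log-log fits (log10 area vs log10
# ug/mL) for ELSD, one curve per compound per day, with linearity
# diagnostics and residual-SD based LOD/LOQ estimates.

suppressPackageStartupMessages(library(qamsvg))

peaks <- read_peak_table("results/peak_table.csv")
fits <- calibrate_peak_table(peaks)
summ <- attr(fits, "summary")
ll <- t(vapply(fits, lod_loq, numeric(2)))
summ$lod_mg_ml <- ll[, "lod"]
summ$loq_mg_ml <- ll[, "loq"]

write_calibration_json(fits, "results/calibration.json")
write.csv(summ, "results/calibration_summary.csv", row.names = FALSE)

cat(sprintf("fitted %d curves; correlation coefficients %.4f-%.4f\n",
            nrow(summ), min(summ$r), max(summ$r)))
poor <- summ[summ$r < 0.999, c("compound", "detector", "day", "r")]
if (nrow(poor)) {
  cat("curves with R < 0.999 (candidates for exclusion):\n")
  print(poor, row.names = FALSE)
}
cat("wrote results/calibration.json and results/calibration_summary.csv\n")
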