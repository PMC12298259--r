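#!/usr/bin/env Rscript
# Stage 3 — relative conversion factors.
#
# For every analyte/marker pair of the per-detector marker assignment,
# computes the factor both ways (slope ratio of the fitted curves;
# mean matched-level response ratio) per day, and the three-day mean.

suppressPackageStartupMessages(library(qamsvg))

peaks <- read_peak_table("results/peak_table.csv")
fits <- calibrate_peak_table(peaks)
markers <- list(PDA = vg_marker_assignment("PDA"),
                ELSD = vg_marker_assignment("ELSD"))

intra <- build_fx_table(fits, peaks, markers, days = 1:3,
                        provenance = "intra_day")
inter <- build_fx_table(fits, peaks, markers, days = 1:3,
                        provenance = "inter_day_mean")
tab <- rbind(cbind(window = "intra_day_1", fx_table_df(intra)),
             cbind(window = "inter_day_mean", fx_table_df(inter)))
write.csv(tab, "results/conversion_factors.csv", row.names = FALSE)

cat("conversion factors (day 1 vs three-day mean):\n")
print(tab[tab$analyte != tab$marker,
          c("window", "analyte", "marker", "detector", "method", "fx")],
      row.names = FALSE, digits = 4)
cat("wrote results/conversion_factors.csv\n")
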