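#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study data.
#
# Emulates the measurement campaign: six-level geometric dilution series
# (factor 0.75) of the five saponin standards on three days, six replicate
# sample preparations of a root-powder extract (100 mg into 5 mL), and a
# three-level spiked-recovery design (80/100/120% of nominal content,
# three preparations each), on both detectors, with 2% relative
# measurement noise. All downstream stages read only the files written
# here.

suppressPackageStartupMessages(library(qamsvg))
dir.create("results", showWarnings = FALSE)

seed <- 2026
contents <- c("G-Rb1" = 1.46, "G-Rd" = 0.96, "G-Rg1" = 3.96,
              "M-R2" = 5.51, "V-R2" = 2.67)
set.seed(seed)

peaks_all <- list(); design_all <- list()
for (det in c("PDA", "ELSD")) {
  models <- vg_detector_models(det, noise_rel = 0.02)
  quantifiable <- names(vg_marker_assignment(det))
  models <- models[quantifiable]
  design <- dilution_design(vg_c1()[quantifiable])
  scn <- qams_scenario(contents[quantifiable], sample_mass = 100,
                       final_volume = 5, seed = seed)
  cal <- simulate_calibration_table(design, models, days = 1:3)
  samp <- simulate_sample_set(scn, models, n_replicates = 6)
  spikes <- make_spike_design(scn, models)
  peaks_all[[det]] <- rbind(cal, samp, spikes$peaks)
  design_all[[det]] <- cbind(detector = det, spikes$design)
}
peaks <- do.call(rbind, peaks_all)
rownames(peaks) <- NULL

write_peak_table(peaks, "results/peak_table.csv")
write.csv(do.call(rbind, design_all), "results/spike_design.csv",
          row.names = FALSE)

cat(sprintf("peak table: %d rows (%d calibration, %d sample, %d spike)\n",
            nrow(peaks), sum(peaks$role == "calibration"),
            sum(peaks$role == "sample"), sum(peaks$role == "spike")))
cat("wrote results/peak_table.csv and results/spike_design.csv\n")
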