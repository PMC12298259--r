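test_that("SMD statistic: definition, boundary and invariances", {
  expect_equal(smd(5.71, 5.71), 0.00)
  expect_equal(round(smd(5.71, 4.13), 2), 27.67)
  expect_equal(smd(4.0, 3.8), 5.00)            # boundary of the 5.00% rule
  expect_equal(smd(4.0, 4.2), 5.00)            # symmetric in the deviation
  expect_error(smd(0, 1), "positive")
  expect_error(smd(-1, 1), "positive")
  # scale invariance
  x <- c(5.1, 4.7); k <- 3.7
  expect_equal(smd(k * x[1], k * x[2]), smd(x[1], x[2]))
  expect_true(all(smd(c(2, 3), c(1.5, 3.3)) >= 0))
})

test_that("RSD: definition, scale invariance and guards", {
  expect_equal(rsd(rep(1, 6)), 0)
  expect_equal(round(rsd(c(2, 4)), 2), 47.14)
  x <- c(1.2, 1.4, 1.1, 1.3)
  expect_equal(rsd(5 * x), rsd(x))
  expect_error(rsd(3), "at least 2")
})

test_that("recovery formula behaves on the content scale", {
  expect_equal(recovery(1.8, 1.0, 0.8), 100.0)
  expect_equal(recovery(1.0, 1.0, 0.8), 0.0)
  expect_error(recovery(1.8, 1.0, 0), "positive")
})

test_that("precision summary: intra/inter-day structure", {
  set.seed(2)
  vals <- 1.46 * (1 + stats::rnorm(6, 0, 0.02))
  # two days with identical value sets: inter-day RSD equals intra-day
  q <- data.frame(compound = "G-Rb1", detector = "PDA", method = "ESM",
                  day = rep(1:2, each = 6), lab = "lab1",
                  content_pct = c(vals, vals), stringsAsFactors = FALSE)
  ps <- precision_summary(q)
  intra <- ps$rsd_pct[ps$grouping == "intra_day"]
  inter <- ps$rsd_pct[ps$grouping == "inter_day"]
  expect_equal(intra[1], intra[2])
  # pooling k = 2 identical sets of n = 6 rescales the sample SD by
  # sqrt(k(n-1)/(kn-1)); up to that Bessel factor inter equals intra
  expect_equal(inter, intra[1] * sqrt(10 / 11), tolerance = 1e-12)
  expect_equal(inter, intra[1], tolerance = 0.05)

  # day 2 shifted +10%: pooled RSD exceeds both intra-day RSDs
  q2 <- q; q2$content_pct[q2$day == 2] <- 1.1 * vals
  ps2 <- precision_summary(q2)
  expect_gt(ps2$rsd_pct[ps2$grouping == "inter_day"],
            max(ps2$rsd_pct[ps2$grouping == "intra_day"]))

  # inter-laboratory grouping appears when labs differ
  q3 <- q; q3$lab <- rep(c("lab1", "lab2"), each = 6); q3$day <- 1
  ps3 <- precision_summary(q3)
  expect_true("inter_laboratory" %in% ps3$grouping)
  expect_error(precision_summary(q[0, ]), "empty")
})

test_that("low-noise synthetic scenario keeps all precision RSDs under 5%", {
  cfg <- qams_config(seed = 31, n_replicates = 6)
  b <- run_pipeline(cfg)
  expect_true(all(b$precision$rsd_pct < 5))
})

test_that("compare_methods mirrors the intra-day agreement pattern", {
  cfg <- qams_config(seed = 17)
  b <- run_pipeline(cfg)
  cmp <- b$comparison

  # slope-factor QAMS agrees with ESM for every analyte (5.00% rule)
  slope <- cmp[cmp$method == "QAMS_slope", ]
  expect_true(all(slope$pass))
  expect_true(all(slope$smd_mean < 1e-8))  # same-day identity

  # intercept-free ratio-factor QAMS is strictly worse for every
  # cross-compound ELSD pairing
  for (an in c("G-Rg1", "V-R2")) {
    s <- cmp[cmp$detector == "ELSD" & cmp$compound == an, ]
    expect_gt(s$smd_mean[s$method == "QAMS_ratio"],
              s$smd_mean[s$method == "QAMS_slope"])
  }
  # the marker itself always shows SMD 0 for both variants
  mk <- cmp[cmp$compound == cmp$marker, ]
  expect_true(all(mk$smd_mean < 1e-10))

  # missing ESM baseline is an error
  noesm <- b$quant[b$quant$method != "ESM" & b$quant$role == "sample", ]
  expect_error(compare_methods(noesm), "no ESM baseline")
})

test_that("spiked recoveries on low-noise drift-free data fall in 80-120%", {
  det <- "ELSD"
  models <- vg_detector_models(det, noise_rel = 0.02)
  mk_map <- vg_marker_assignment(det)
  models <- models[names(mk_map)]
  contents <- c("G-Rb1" = 1.46, "G-Rg1" = 3.96, "M-R2" = 5.51,
                "V-R2" = 2.67)
  scn <- qams_scenario(contents, seed = 23)
  design <- dilution_design(vg_c1()[names(models)])
  set.seed(23)
  sp <- make_spike_design(scn, models)
  peaks <- rbind(simulate_calibration_table(design, models),
                 simulate_sample_set(scn, models, n_replicates = 3),
                 sp$peaks)
  fits <- calibrate_peak_table(peaks)
  factors <- build_fx_table(fits, peaks, markers = list(ELSD = mk_map))
  quant <- quantify_samples(peaks, fits, factors, list(ELSD = mk_map),
                            volume_ml = 5, mass_mg = 100)
  rec <- recovery_summary(quant[quant$role == "spike", ],
                          quant[quant$role == "sample", ], sp$design)
  rec_slope <- rec[rec$method %in% c("ESM", "QAMS_slope"), ]
  expect_equal(nrow(rec_slope), 2 * 9 * length(contents))
  expect_true(all(rec_slope$recovery_pct > 80 &
                  rec_slope$recovery_pct < 120))
})
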