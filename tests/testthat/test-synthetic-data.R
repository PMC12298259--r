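test_that("dilution series follows the geometric design and printed ranges", {
  d <- dilution_design(vg_c1())
  s <- make_dilution_series(d, "G-Rb1")
  expect_equal(s, 0.36 * 0.75^(0:5))
  expect_equal(round(s[6], 2), 0.09)  # lower bound of the calibrated range
  expect_equal(round(make_dilution_series(d, "V-R2")[6], 2), 0.19)

  # strictly decreasing, spans exactly [c1 * f^(n-1), c1]
  for (cp in names(vg_c1())) {
    s <- make_dilution_series(d, cp)
    expect_true(all(diff(s) < 0))
    expect_equal(range(s), c(vg_c1()[[cp]] * 0.75^5, vg_c1()[[cp]]))
  }

  # printed range lower bounds for all five compounds at 2 dp
  cal <- vg_reference_calibration()
  for (i in seq_len(nrow(cal))) {
    expect_equal(round(make_dilution_series(d, cal$compound[i])[6], 2),
                 cal$range_low[i])
  }

  # identity dilution and unknown compound
  expect_equal(make_dilution_series(dilution_design(c(a = 2), 1), "a"),
               rep(2, 6))
  expect_error(make_dilution_series(d, "nope"), "unknown compound")
})

test_that("noise-free simulated areas sit exactly on the generating lines", {
  pda <- detector_model("PDA", 10175, 50838)
  expect_equal(response_area(pda, 0.36), 10175 * 0.36 + 50838)  # 54501
  ser <- simulate_calibration(c(0.36, 0.27), pda)
  expect_equal(ser$peak_area, c(54501, 10175 * 0.27 + 50838))

  elsd <- detector_model("ELSD", 1.4371, 0.9450)
  # 0.36 mg/mL = 360 ug/mL
  expect_equal(log10(response_area(elsd, 0.36)),
               1.4371 * log10(360) + 0.9450)
  expect_equal(round(log10(response_area(elsd, 0.36)), 4), 4.6187)
  expect_error(response_area(pda, -1), "positive")
})

test_that("simulation is reproducible under a fixed seed", {
  m <- detector_model("ELSD", 1.4371, 0.9450, noise_rel = 0.02)
  conc <- make_dilution_series(dilution_design(vg_c1()), "G-Rb1")
  s1 <- simulate_calibration(conc, m, seed = 42)
  s2 <- simulate_calibration(conc, m, seed = 42)
  expect_identical(s1, s2)
  s3 <- simulate_calibration(conc, m, seed = 43)
  expect_false(identical(s1$peak_area, s3$peak_area))
  expect_true(all(s1$peak_area > 0))  # log-domain noise keeps areas positive

  scn <- qams_scenario(c("G-Rb1" = 1.46), seed = 5)
  a <- simulate_sample_set(scn, list("G-Rb1" = m), n_replicates = 6, seed = 5)
  b <- simulate_sample_set(scn, list("G-Rb1" = m), n_replicates = 6, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 6L)
  expect_gt(rsd(a$peak_area), 0)
})

test_that("scenario content maps to solution concentration by H = V*C/m*100", {
  scn <- qams_scenario(c("G-Rb1" = 5.00), sample_mass = 100,
                       final_volume = 5, seed = 1)
  expect_equal(true_concentration(scn, "G-Rb1"), 1.00)
  expect_error(true_concentration(scn, "G-Rd"), "no true content")

  # drift factor 1 and zero noise: area equals the calibration line at C
  m <- detector_model("PDA", 10175, 50838)
  rows <- simulate_sample_set(scn, list("G-Rb1" = m), n_replicates = 2)
  expect_equal(rows$peak_area, rep(10175 * 1.00 + 50838, 2))

  # drift multiplies the noise-free response
  scn_d <- qams_scenario(c("G-Rb1" = 5.00), seed = 1,
                         day_drift = list("2" = c("G-Rb1" = 1.1)))
  r2 <- simulate_sample_set(scn_d, list("G-Rb1" = m), n_replicates = 1,
                            day = 2)
  expect_equal(r2$peak_area, 1.1 * (10175 + 50838))
})

test_that("noise-free simulate-quantify round trip recovers true contents", {
  for (det in c("PDA", "ELSD")) {
    models <- vg_detector_models(det)
    quantifiable <- names(vg_marker_assignment(det))
    models <- models[quantifiable]
    contents <- c("G-Rb1" = 1.46, "G-Rd" = 0.50, "G-Rg1" = 3.96,
                  "M-R2" = 5.51, "V-R2" = 2.67)[quantifiable]
    scn <- qams_scenario(contents, seed = 3)
    design <- dilution_design(vg_c1()[quantifiable])
    peaks <- rbind(
      simulate_calibration_table(design, models),
      simulate_sample_set(scn, models, n_replicates = 1)
    )
    fits <- calibrate_peak_table(peaks)
    for (cp in quantifiable) {
      fit <- get_fit(fits, cp, det, 1)
      area <- peaks$peak_area[peaks$role == "sample" & peaks$compound == cp]
      conc <- if (det == "PDA") esm_conc_linear(area, fit) else
        esm_conc_log(area, fit)
      h <- content_percent(as.numeric(conc), 5, 100)
      expect_equal(h, unname(contents[cp]), tolerance = 1e-9)
    }
  }
})

test_that("spike design yields 9 records per compound with known additions", {
  scn <- qams_scenario(c("G-Rb1" = 1.46), seed = 11)
  m <- list("G-Rb1" = detector_model("PDA", 10175, 50838))
  sp <- make_spike_design(scn, m, seed = 11)
  expect_equal(nrow(sp$peaks), 9L)
  expect_equal(nrow(sp$design), 9L)
  expect_equal(sort(unique(sp$design$spike_level)), c(0.8, 1.0, 1.2))
  expect_equal(sp$design$added_content_pct,
               sp$design$spike_level * 1.46)
  expect_true(all(table(sp$design$spike_level) == 3))

  scn0 <- qams_scenario(c("G-Rb1" = 1.46), spike_levels = c(0, 1), seed = 1)
  expect_error(make_spike_design(scn0, m), "undefined")
})
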