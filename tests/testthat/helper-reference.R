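# Shared fixtures built in code: noise-free series and fits parameterised
# from the package's bundled reference calibration table.

ref_cal <- function(compound, detector) {
  cal <- vg_reference_calibration()
  cal[cal$compound == compound & cal$detector == detector, ]
}

ref_model <- function(compound, detector, noise_rel = 0) {
  rc <- ref_cal(compound, detector)
  detector_model(detector, rc$slope, rc$intercept, noise_rel = noise_rel)
}

ref_fit <- function(compound, detector) {
  rc <- ref_cal(compound, detector)
  calibration_fit(
    model_kind = if (detector == "PDA") "linear" else "loglog",
    slope = rc$slope, intercept = rc$intercept, r = rc$r,
    residual_sd = 0, n_points = 6L,
    conc_unit = if (detector == "PDA") "mg/mL" else "ug/mL",
    valid_range = c(rc$range_low, rc$range_high)
  )
}

# Noise-free six-level calibration series from the reference line.
ref_series <- function(compound, detector) {
  conc <- make_dilution_series(dilution_design(vg_c1()), compound)
  model <- ref_model(compound, detector)
  data.frame(concentration = conc,
             peak_area = response_area(model, conc))
}

# Independent closed-form oracle for the log-domain response-ratio
# factor: per level, (a_x + b_x/log10(C_x)) / (a_s + b_s/log10(C_s))
# with concentrations in ug/mL, averaged over levels. Evaluates the
# printed regression lines directly, bypassing the package's area
# simulation and ratio code paths.
oracle_fx_log <- function(analyte, marker) {
  ax <- ref_cal(analyte, "ELSD"); as_ <- ref_cal(marker, "ELSD")
  cx <- 1000 * make_dilution_series(dilution_design(vg_c1()), analyte)
  cs <- 1000 * make_dilution_series(dilution_design(vg_c1()), marker)
  mean((ax$slope + ax$intercept / log10(cx)) /
       (as_$slope + as_$intercept / log10(cs)))
}
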