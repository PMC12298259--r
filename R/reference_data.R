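#' Reference compounds for Panax vietnamensis saponin quantification
#'
#' The five major saponins quantified in Vietnamese ginseng (VG) root, with
#' the certified purity of the primary reference standards and the skeleton
#' class each compound belongs to: protopanaxadiol (PPD), protopanaxatriol
#' (PPT) or ocotillol (OT). The OT-type saponins lack the side-chain double
#' bond and are therefore (nearly) invisible to a UV/PDA detector.
#'
#' @return A data.frame with columns `compound`, `skeleton`, `purity`
#'   (mass fraction in (0, 1]).
#' @export
#' @examples
#' vg_compounds()
vg_compounds <- function() {
  data.frame(
    compound = c("G-Rb1", "G-Rd", "G-Rg1", "M-R2", "V-R2"),
    skeleton = c("PPD", "PPD", "PPT", "OT", "OT"),
    purity   = c(0.9917, 0.9448, 0.9643, 0.9886, 0.9763),
    stringsAsFactors = FALSE
  )
}

#' Stock (C1) standard concentrations
#'
#' Top-level concentrations of the standard dilution series, in mg/mL.
#' Levels C2..C6 are obtained by serial dilution with factor 0.75
#' (see [dilution_design()]).
#'
#' @return Named numeric vector of C1 concentrations (mg/mL).
#' @export
vg_c1 <- function() {
  c("G-Rb1" = 0.36, "G-Rd" = 0.17, "G-Rg1" = 1.39,
    "M-R2" = 2.30, "V-R2" = 0.81)
}

#' Published calibration parameters for the five VG saponins
#'
#' Regression parameters of the detector response curves: for the PDA
#' detector the model is linear, `area = slope * C(mg/mL) + intercept`;
#' for the ELSD the model is a power law fitted in log-log coordinates,
#' `log10(area) = slope * log10(C in ug/mL) + intercept`. `r` is the
#' correlation coefficient reported with each curve; `range_low` /
#' `range_high` bound the calibrated concentration range in mg/mL.
#' V-R2 gives no usable PDA signal (no chromophore) and is absent from the
#' PDA block; G-Rd on the ELSD has poor linearity and is excluded from
#' ELSD quantification downstream.
#'
#' @return A data.frame with one row per (compound, detector) and columns
#'   `compound`, `detector`, `slope`, `intercept`, `r`, `range_low`,
#'   `range_high`.
#' @export
#' @examples
#' subset(vg_reference_calibration(), detector == "ELSD")
vg_reference_calibration <- function() {
  rbind(
    data.frame(
      compound  = c("G-Rg1", "M-R2", "G-Rb1", "G-Rd"),
      detector  = "PDA",
      slope     = c(13426, 374, 10175, 11035),
      intercept = c(846186, 14146, 50838, 17292),
      r         = c(0.9998, 0.9999, 0.9999, 1.0000),
      range_low = c(0.33, 0.55, 0.09, 0.04),
      range_high = c(1.39, 2.30, 0.36, 0.17),
      stringsAsFactors = FALSE
    ),
    data.frame(
      compound  = c("G-Rg1", "M-R2", "V-R2", "G-Rb1", "G-Rd"),
      detector  = "ELSD",
      slope     = c(1.3722, 1.3223, 1.3942, 1.4371, 1.1121),
      intercept = c(1.0728, 1.2472, 1.0544, 0.9450, 1.3828),
      r         = c(0.9999, 0.9996, 0.9999, 0.9998, 0.9937),
      range_low = c(0.33, 0.55, 0.19, 0.09, 0.04),
      range_high = c(1.39, 2.30, 0.81, 0.36, 0.17),
      stringsAsFactors = FALSE
    )
  )
}

#' Default single-marker assignment per detector
#'
#' On the PDA detector G-Rb1 serves as the single marker for all UV-active
#' analytes (G-Rb1, G-Rd, G-Rg1, M-R2). On the ELSD two markers are used:
#' G-Rb1 for the PPD/PPT saponins (G-Rb1, G-Rg1) and M-R2 for the
#' ocotillol-type saponins (M-R2, V-R2), because the ELSD response of the
#' OT saponins tracks M-R2 far better than G-Rb1.
#'
#' @param detector `"PDA"` or `"ELSD"`.
#' @return Named character vector mapping analyte -> marker.
#' @export
#' @examples
#' vg_marker_assignment("ELSD")
vg_marker_assignment <- function(detector = c("PDA", "ELSD")) {
  detector <- match.arg(detector)
  if (detector == "PDA") {
    c("G-Rb1" = "G-Rb1", "G-Rd" = "G-Rb1",
      "G-Rg1" = "G-Rb1", "M-R2" = "G-Rb1")
  } else {
    c("G-Rb1" = "G-Rb1", "G-Rg1" = "G-Rb1",
      "M-R2" = "M-R2", "V-R2" = "M-R2")
  }
}

#' Detector response models parameterised from the reference calibration
#'
#' Builds one [detector_model()] per compound for the requested detector,
#' using the published slopes/intercepts as the generating truth for
#' synthetic data.
#'
#' @param detector `"PDA"` or `"ELSD"`.
#' @param noise_rel Relative measurement noise (fraction, e.g. 0.02 for 2%);
#'   mapped to the detector's native noise parameterisation. Default 0
#'   (noise-free).
#' @return Named list of `detector_model` objects keyed by compound.
#' @export
vg_detector_models <- function(detector = c("PDA", "ELSD"), noise_rel = 0) {
  detector <- match.arg(detector)
  cal <- vg_reference_calibration()
  cal <- cal[cal$detector == detector, ]
  models <- lapply(seq_len(nrow(cal)), function(i) {
    detector_model(kind = detector,
                   slope = cal$slope[i],
                   intercept = cal$intercept[i],
                   noise_rel = noise_rel)
  })
  names(models) <- cal$compound
  models
}
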