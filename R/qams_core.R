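#' Relative conversion factor between an analyte and a single marker
#'
#' The scalar F_x relating an analyte's detector response to the single
#' marker's. Two constructions exist: the slope ratio of the two
#' calibration curves (`method = "slope_ratio"`), and the mean ratio of
#' per-level response ratios along matched dilution levels
#' (`method = "response_ratio"`). A marker's factor against itself is
#' exactly 1.
#'
#' @param analyte,marker Compound identifiers.
#' @param detector Detector the factor applies to.
#' @param method `"slope_ratio"` or `"response_ratio"`.
#' @param value The factor F_x (> 0, unitless).
#' @param provenance Free-form provenance tag, e.g. `"intra_day(1)"` or
#'   `"inter_day_mean(1,2,3)"`.
#' @return Object of class `conversion_factor`.
#' @export
conversion_factor <- function(analyte, marker, detector, method, value,
                              provenance = "intra_day") {
  stopifnot(method %in% c("slope_ratio", "response_ratio"),
            is.numeric(value), length(value) == 1L, value > 0)
  if (analyte == marker && abs(value - 1) > 1e-12) {
    stop("a marker's conversion factor against itself must be exactly 1")
  }
  structure(
    list(analyte = analyte, marker = marker, detector = detector,
         method = method, value = value, provenance = provenance),
    class = "conversion_factor"
  )
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("<conversion_factor> F(%s / %s, %s, %s) = %.4f  [%s]\n",
              x$analyte, x$marker, x$detector, x$method, x$value,
              x$provenance))
  invisible(x)
}

#' Conversion factor from the ratio of calibration slopes
#'
#' `F_x = a_x / a_s`, the analyte's calibration slope over the marker's.
#' Both fits must be of the same model kind (and hence the same detector
#' convention): the ratio of a linear and a log-log slope is meaningless.
#'
#' @param fit_x Analyte [calibration_fit()].
#' @param fit_s Marker [calibration_fit()].
#' @param analyte,marker Compound identifiers (marker defaults to
#'   `"marker"`).
#' @param detector Detector tag (defaults from the model kind).
#' @param provenance Provenance tag.
#' @return A [conversion_factor()] with `method = "slope_ratio"`.
#' @export
#' @examples
#' f_x <- calibration_fit("linear", 13426, 846186, 1, 0, 6, "mg/mL", c(0.33, 1.39))
#' f_s <- calibration_fit("linear", 10175, 50838, 1, 0, 6, "mg/mL", c(0.09, 0.36))
#' fx_slope_ratio(f_x, f_s, "G-Rg1", "G-Rb1")$value  # 1.3195 -> 1.32
fx_slope_ratio <- function(fit_x, fit_s, analyte = "analyte",
                           marker = "marker", detector = NULL,
                           provenance = "intra_day") {
  stopifnot(inherits(fit_x, "calibration_fit"),
            inherits(fit_s, "calibration_fit"))
  if (fit_x$model_kind != fit_s$model_kind) {
    stop("slope-ratio factor requires fits of the same model kind")
  }
  if (fit_s$slope == 0) stop("marker slope is zero")
  if (is.null(detector)) {
    detector <- if (fit_x$model_kind == "linear") "PDA" else "ELSD"
  }
  value <- if (analyte == marker) 1 else fit_x$slope / fit_s$slope
  conversion_factor(analyte, marker, detector, "slope_ratio", value,
                    provenance)
}

#' Conversion factor from matched-level response ratios
#'
#' For each matched dilution level i, the analyte's specific response is
#' divided by the marker's and the factor is the arithmetic mean over
#' levels. In the linear domain the specific response is `A/C` with C in
#' mg/mL; in the log domain it is `log10(A)/log10(C)` with C converted to
#' ug/mL first (a level with C = 1 ug/mL would make the denominator zero
#' and is rejected).
#'
#' @param series_x,series_s Calibration series data.frames (columns
#'   `concentration` in mg/mL and `peak_area`) with equal numbers of
#'   levels, measured on the same day.
#' @param domain `"linear"` or `"log"`.
#' @param analyte,marker,detector,provenance Identity tags.
#' @return A [conversion_factor()] with `method = "response_ratio"`.
#' @export
fx_response_ratio <- function(series_x, series_s,
                              domain = c("linear", "log"),
                              analyte = "analyte", marker = "marker",
                              detector = NULL, provenance = "intra_day") {
  domain <- match.arg(domain)
  stopifnot(is.data.frame(series_x), is.data.frame(series_s))
  if (nrow(series_x) != nrow(series_s)) {
    stop("response-ratio factor requires matched level counts")
  }
  if ("day" %in% names(series_x) && "day" %in% names(series_s) &&
      !identical(unique(series_x$day), unique(series_s$day))) {
    stop("analyte and marker series must come from the same day")
  }
  if (is.null(detector)) {
    detector <- if (domain == "linear") "PDA" else "ELSD"
  }
  if (domain == "linear") {
    per_level <- (series_x$peak_area / series_x$concentration) /
      (series_s$peak_area / series_s$concentration)
  } else {
    cx <- 1000 * series_x$concentration
    cs <- 1000 * series_s$concentration
    if (any(log10(cx) == 0) || any(log10(cs) == 0)) {
      stop("a level at 1 ug/mL makes log10(C) = 0: response ratio undefined")
    }
    per_level <- (log10(series_x$peak_area) / log10(cx)) /
      (log10(series_s$peak_area) / log10(cs))
  }
  value <- if (analyte == marker) 1 else mean(per_level)
  out <- conversion_factor(analyte, marker, detector, "response_ratio",
                           value, provenance)
  out$per_level <- per_level
  out
}

#' Average conversion factors across days
#'
#' Arithmetic mean of daily factors sharing the same analyte, marker,
#' detector and method; the result carries inter-day provenance. This is
#' the "mean of per-day factors" construction (not a ratio of averaged
#' slopes).
#'
#' @param factors List of [conversion_factor()]s.
#' @return A [conversion_factor()] with `provenance = "inter_day_mean"`.
#' @export
average_fx <- function(factors) {
  stopifnot(length(factors) >= 1L,
            all(vapply(factors, inherits, logical(1), "conversion_factor")))
  ids <- unique(t(vapply(factors, function(f)
    c(f$analyte, f$marker, f$detector, f$method), character(4))))
  if (nrow(ids) != 1L) {
    stop("cannot average conversion factors with mixed identities")
  }
  f1 <- factors[[1]]
  conversion_factor(
    f1$analyte, f1$marker, f1$detector, f1$method,
    mean(vapply(factors, `[[`, numeric(1), "value")),
    provenance = sprintf("inter_day_mean(n=%d)", length(factors))
  )
}

.fx_value <- function(fx) {
  if (inherits(fx, "conversion_factor")) fx$value else {
    stopifnot(is.numeric(fx), length(fx) == 1L, fx > 0)
    fx
  }
}

# Attach an out-of-range flag without clamping the value.
.flag_range <- function(conc, fit) {
  flag <- conc < fit$valid_range[1] | conc > fit$valid_range[2] | conc < 0
  attr(conc, "out_of_range") <- flag
  conc
}

#' External-standard concentration from a linear fit
#'
#' Inverts the analyte's own linear calibration curve:
#' `C = (A - b) / a`. Results outside the fit's calibrated range
#' (including negative concentrations from areas below the intercept) are
#' flagged in the `"out_of_range"` attribute, never clamped.
#'
#' @param area Peak area(s).
#' @param fit The analyte's linear [calibration_fit()].
#' @return Concentration(s) in mg/mL with an `out_of_range` attribute.
#' @export
esm_conc_linear <- function(area, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$model_kind != "linear") stop("fit must be linear (PDA convention)")
  if (fit$slope == 0) stop("zero slope")
  .flag_range((area - fit$intercept) / fit$slope, fit)
}

#' Single-marker (QAMS) concentration, linear domain
#'
#' Indirect quantification of an analyte from the marker's fresh
#' measurement (`area_s` at known `conc_s`) and the conversion factor.
#' Without intercepts the zero-intercept form is used:
#' `C_x = A_x * C_s / (F * A_s)`. With stored intercepts `b_x`, `b_s`
#' (from previously established calibration curves) the
#' intercept-corrected form is used:
#' `C_x = (A_x - b_x) * C_s / ((A_s - b_s) * F)`, which reduces exactly
#' to the external-standard result when `F` is the slope ratio and the
#' marker's area lies on its own curve.
#'
#' @param area_x Analyte peak area(s).
#' @param area_s Marker peak area (single fresh measurement).
#' @param conc_s Marker concentration in mg/mL (> 0).
#' @param fx A [conversion_factor()] or bare positive number.
#' @param b_x,b_s Stored intercepts; both `NULL` for the zero-intercept
#'   form.
#' @return Concentration(s) in mg/mL.
#' @export
qams_conc_linear <- function(area_x, area_s, conc_s, fx,
                             b_x = NULL, b_s = NULL) {
  f <- .fx_value(fx)
  stopifnot(conc_s > 0)
  if (is.null(b_x) != is.null(b_s)) {
    stop("provide both intercepts (b_x, b_s) or neither")
  }
  if (is.null(b_x)) {
    if (area_s <= 0) stop("marker area must be positive")
    area_x * conc_s / (f * area_s)
  } else {
    if (area_s - b_s == 0) stop("marker area equals stored intercept")
    (area_x - b_x) * conc_s / ((area_s - b_s) * f)
  }
}

#' External-standard concentration from a log-log fit
#'
#' Inverts the analyte's own power-law curve:
#' `C = 10^((log10(A) - b) / a - 3)` — the `-3` converts the fit's ug/mL
#' convention back to mg/mL.
#'
#' @param area Peak area(s), > 0.
#' @param fit The analyte's log-log [calibration_fit()].
#' @return Concentration(s) in mg/mL with an `out_of_range` attribute.
#' @export
esm_conc_log <- function(area, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$model_kind != "loglog") stop("fit must be loglog (ELSD convention)")
  if (any(area <= 0)) stop("peak area must be positive for the log model")
  .flag_range(10^((log10(area) - fit$intercept) / fit$slope - 3), fit)
}

#' Single-marker (QAMS) concentration, log domain
#'
#' Indirect ELSD quantification from the marker's fresh measurement, with
#' the marker concentration in ug/mL (the ELSD convention). Without
#' intercepts:
#' `C_x = 10^(log10(A_x) * log10(C_s) / (F * log10(A_s)) - 3)`.
#' With stored intercepts:
#' `C_x = 10^((log10(A_x) - b_x) * log10(C_s) / ((log10(A_s) - b_s) * F) - 3)`,
#' which reduces exactly to the external-standard result when `F` is the
#' slope ratio and the marker's area lies on its own curve.
#'
#' @param area_x Analyte peak area(s), > 0.
#' @param area_s Marker peak area, > 0.
#' @param conc_s_ug Marker concentration in ug/mL (`log10` must be
#'   nonzero).
#' @param fx A [conversion_factor()] or bare positive number.
#' @param b_x,b_s Stored log-domain intercepts; both `NULL` for the
#'   intercept-free form.
#' @return Concentration(s) in mg/mL.
#' @export
qams_conc_log <- function(area_x, area_s, conc_s_ug, fx,
                          b_x = NULL, b_s = NULL) {
  f <- .fx_value(fx)
  stopifnot(all(area_x > 0), area_s > 0, conc_s_ug > 0)
  if (log10(conc_s_ug) == 0) {
    stop("marker at 1 ug/mL makes log10(C_s) = 0: QAMS log form undefined")
  }
  if (is.null(b_x) != is.null(b_s)) {
    stop("provide both intercepts (b_x, b_s) or neither")
  }
  if (is.null(b_x)) {
    if (log10(area_s) == 0) stop("log10 of marker area is zero")
    10^(log10(area_x) * log10(conc_s_ug) / (f * log10(area_s)) - 3)
  } else {
    denom <- log10(area_s) - b_s
    if (denom == 0) stop("log10 marker area equals stored intercept")
    10^((log10(area_x) - b_x) * log10(conc_s_ug) / (denom * f) - 3)
  }
}

#' Dry-weight content from solution concentration
#'
#' `H(%) = V * C / m * 100` with solution volume V (mL), concentration C
#' (mg/mL) and dry sample mass m (mg).
#'
#' @param conc_mg_ml Concentration(s) in mg/mL.
#' @param volume_ml Final solution volume in mL (> 0).
#' @param mass_mg Dry sample mass in mg (> 0).
#' @return Content in percent dry weight.
#' @export
#' @examples
#' content_percent(1.0, 5, 100)  # 5%
content_percent <- function(conc_mg_ml, volume_ml, mass_mg) {
  if (volume_ml <= 0 || mass_mg <= 0) {
    stop("volume and mass must be positive")
  }
  volume_ml * conc_mg_ml / mass_mg * 100
}

#' Quantify sample measurements by ESM and both QAMS variants
#'
#' For every sample/spike row of a peak table, computes the concentration
#' and dry-weight content three ways: `ESM` (the analyte's own
#' calibration curve), `QAMS_slope` (slope-ratio factor with stored
#' intercepts — the intercept-corrected single-marker equations) and
#' `QAMS_ratio` (response-ratio factor, intercept-free single-marker
#' equations).
#'
#' The single-marker equations need one fresh marker measurement
#' `(A_s, C_s)`. By default this is the marker's own peak in the same
#' chromatogram (same sample, replicate, day, lab): its area is read
#' directly and its concentration is obtained from the marker's stored
#' calibration curve — the one curve a QAMS practitioner actually has.
#' This is what makes the marker's own QAMS result coincide exactly with
#' its ESM result, and makes the intercept-corrected slope-factor
#' equations algebraically identical to ESM whenever factor and stored
#' curves come from the same day. Alternatively `marker_obs` supplies an
#' external standard observation per (marker, detector).
#'
#' @param peaks Peak-table data.frame; rows with `role` in `roles` are
#'   quantified.
#' @param fits Result of [calibrate_peak_table()] (the stored curves;
#'   QAMS uses only the marker's curve parameters and the analyte's
#'   stored intercept and factor).
#' @param factors Named list of [conversion_factor()]s keyed
#'   `"analyte|marker|detector|method"` (see [build_fx_table()]).
#' @param markers Named character vector analyte -> marker per detector,
#'   as a list keyed by detector (see [vg_marker_assignment()]).
#' @param volume_ml,mass_mg Sample preparation parameters for the content
#'   formula.
#' @param fit_day Which day's stored curves to use (default 1).
#' @param roles Peak-table roles to quantify (default sample and spike).
#' @param marker_obs Optional data.frame of external marker measurements
#'   with columns `compound`, `detector`, `conc_mg_ml`, `peak_area` (one
#'   row per marker/detector); `NULL` (default) uses the in-sample
#'   marker peak.
#' @return Long data.frame: `sample_id`, `replicate`, `compound`,
#'   `detector`, `method` (ESM / QAMS_slope / QAMS_ratio), `marker`,
#'   `conc_mg_ml`, `content_pct`, `out_of_range`.
#' @export
quantify_samples <- function(peaks, fits, factors, markers,
                             volume_ml, mass_mg, fit_day = 1L,
                             roles = c("sample", "spike"),
                             marker_obs = NULL) {
  rows <- peaks[peaks$role %in% roles, ]
  if (!nrow(rows)) stop("no rows with the requested roles to quantify")
  out <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    det <- r$detector
    mk_map <- markers[[det]]
    if (is.null(mk_map) || !r$compound %in% names(mk_map)) {
      stop(sprintf("no marker assigned for %s on %s", r$compound, det))
    }
    mk <- mk_map[[r$compound]]
    fit_x <- get_fit(fits, r$compound, det, fit_day)
    fit_s <- get_fit(fits, mk, det, fit_day)
    if (is.null(marker_obs)) {
      mrow <- peaks[peaks$sample_id == r$sample_id &
                    peaks$replicate == r$replicate &
                    peaks$day == r$day & peaks$lab == r$lab &
                    peaks$detector == det & peaks$compound == mk, ]
      if (nrow(mrow) != 1L) {
        stop(sprintf("no in-sample marker peak for %s on %s in %s/rep %s",
                     mk, det, r$sample_id, r$replicate))
      }
      a_s <- mrow$peak_area
      c_s <- if (det == "PDA") as.numeric(esm_conc_linear(a_s, fit_s)) else
        as.numeric(esm_conc_log(a_s, fit_s))
    } else {
      mo <- marker_obs[marker_obs$compound == mk &
                       marker_obs$detector == det, ]
      if (nrow(mo) != 1L) {
        stop(sprintf("need exactly one marker observation for %s on %s",
                     mk, det))
      }
      a_s <- mo$peak_area
      c_s <- mo$conc_mg_ml
    }
    f_slope <- .lookup_fx(factors, r$compound, mk, det, "slope_ratio")
    f_ratio <- .lookup_fx(factors, r$compound, mk, det, "response_ratio")
    if (det == "PDA") {
      c_esm <- esm_conc_linear(r$peak_area, fit_x)
      c_slp <- qams_conc_linear(r$peak_area, a_s, c_s,
                                f_slope, b_x = fit_x$intercept,
                                b_s = fit_s$intercept)
      c_rat <- qams_conc_linear(r$peak_area, a_s, c_s, f_ratio)
    } else {
      c_esm <- esm_conc_log(r$peak_area, fit_x)
      c_slp <- qams_conc_log(r$peak_area, a_s, 1000 * c_s, f_slope,
                             b_x = fit_x$intercept, b_s = fit_s$intercept)
      c_rat <- qams_conc_log(r$peak_area, a_s, 1000 * c_s, f_ratio)
    }
    concs <- c(ESM = as.numeric(c_esm), QAMS_slope = c_slp,
               QAMS_ratio = c_rat)
    out[[length(out) + 1L]] <- data.frame(
      sample_id = r$sample_id, replicate = r$replicate,
      compound = r$compound, detector = det,
      method = names(concs), marker = mk,
      conc_mg_ml = unname(concs),
      content_pct = content_percent(unname(concs), volume_ml, mass_mg),
      out_of_range = rep(attr(c_esm, "out_of_range"), length(concs)),
      day = r$day, lab = r$lab, role = r$role,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.lookup_fx <- function(factors, analyte, marker, detector, method) {
  key <- sprintf("%s|%s|%s|%s", analyte, marker, detector, method)
  f <- factors[[key]]
  if (is.null(f)) {
    stop(sprintf("no conversion factor for %s", key))
  }
  f
}

#' Build a keyed table of conversion factors
#'
#' Computes slope-ratio and response-ratio conversion factors for every
#' analyte/marker pair of a marker assignment, per day, from fitted
#' curves and calibration series; optionally averages across days.
#'
#' @param fits Result of [calibrate_peak_table()].
#' @param peaks Peak table with the calibration rows (needed for the
#'   response-ratio construction).
#' @param markers List keyed by detector of named vectors analyte ->
#'   marker.
#' @param days Days to compute per-day factors for.
#' @param provenance `"intra_day"` (factors of `days[1]`) or
#'   `"inter_day_mean"` (average across `days`).
#' @return Named list of [conversion_factor()]s keyed
#'   `"analyte|marker|detector|method"`.
#' @export
build_fx_table <- function(fits, peaks, markers, days = 1L,
                           provenance = c("intra_day", "inter_day_mean")) {
  provenance <- match.arg(provenance)
  cal <- peaks[peaks$role == "calibration", ]
  out <- list()
  for (det in names(markers)) {
    mk_map <- markers[[det]]
    for (an in names(mk_map)) {
      mk <- mk_map[[an]]
      slope_by_day <- list(); ratio_by_day <- list()
      for (day in days) {
        fit_x <- get_fit(fits, an, det, day)
        fit_s <- get_fit(fits, mk, det, day)
        slope_by_day[[as.character(day)]] <-
          fx_slope_ratio(fit_x, fit_s, an, mk, det,
                         sprintf("intra_day(%s)", day))
        sx <- cal[cal$compound == an & cal$detector == det &
                  cal$day == day, ]
        ss <- cal[cal$compound == mk & cal$detector == det &
                  cal$day == day, ]
        ser_x <- data.frame(concentration = sx$known_conc_mg_per_ml,
                            peak_area = sx$peak_area)
        ser_s <- data.frame(concentration = ss$known_conc_mg_per_ml,
                            peak_area = ss$peak_area)
        ratio_by_day[[as.character(day)]] <-
          fx_response_ratio(ser_x, ser_s,
                            domain = if (det == "PDA") "linear" else "log",
                            analyte = an, marker = mk, detector = det,
                            provenance = sprintf("intra_day(%s)", day))
      }
      f_slope <- if (provenance == "intra_day") slope_by_day[[1]] else
        average_fx(slope_by_day)
      f_ratio <- if (provenance == "intra_day") ratio_by_day[[1]] else
        average_fx(ratio_by_day)
      out[[sprintf("%s|%s|%s|slope_ratio", an, mk, det)]] <- f_slope
      out[[sprintf("%s|%s|%s|response_ratio", an, mk, det)]] <- f_ratio
    }
  }
  out
}

#' Flatten a conversion-factor table to a data.frame
#'
#' @param factors Named list of [conversion_factor()]s.
#' @return data.frame with one row per factor.
#' @export
fx_table_df <- function(factors) {
  df <- do.call(rbind, lapply(factors, function(f) {
    data.frame(analyte = f$analyte, marker = f$marker,
               detector = f$detector, method = f$method,
               fx = f$value, provenance = f$provenance,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}
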