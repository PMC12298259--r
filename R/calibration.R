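#' Calibration fit for a detector response curve
#'
#' Constructor for the fitted-curve container used throughout the
#' package. Users normally obtain these from [fit_linear()] or
#' [fit_loglog()] rather than calling this directly.
#'
#' @param model_kind `"linear"` (PDA convention, concentration in mg/mL)
#'   or `"loglog"` (ELSD convention, concentration in ug/mL before
#'   log10).
#' @param slope,intercept Fitted coefficients.
#' @param r Correlation coefficient between response and predictor (in
#'   the fitting domain).
#' @param residual_sd Residual standard deviation of the fit (fitting
#'   domain units).
#' @param n_points Number of calibration points used.
#' @param conc_unit Concentration unit used in the fit.
#' @param valid_range Range of fitted concentrations, mg/mL.
#' @return Object of class `calibration_fit`.
#' @export
calibration_fit <- function(model_kind, slope, intercept, r, residual_sd,
                            n_points, conc_unit, valid_range) {
  stopifnot(model_kind %in% c("linear", "loglog"),
            n_points >= 3L, r >= -1 - 1e-12, r <= 1 + 1e-12,
            length(valid_range) == 2L)
  structure(
    list(model_kind = model_kind, slope = slope, intercept = intercept,
         r = r, residual_sd = residual_sd, n_points = as.integer(n_points),
         conc_unit = conc_unit, valid_range = valid_range),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit %s> y = %.6g x + %.6g  (R = %.4f, s = %.4g, n = %d, C in %s, range %.4g-%.4g mg/mL)\n",
              x$model_kind, x$slope, x$intercept, x$r, x$residual_sd,
              x$n_points, x$conc_unit, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

.check_points <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "peak_area") %in% names(points)))
  if (any(points$concentration <= 0)) {
    stop("calibration concentrations must be strictly positive")
  }
  if (length(unique(points$concentration)) < 3L) {
    stop("calibration requires at least 3 distinct concentrations")
  }
  points
}

#' Fit a linear (PDA) calibration curve
#'
#' Ordinary least squares of peak area on concentration in mg/mL:
#' `area = a * C + b`. Unweighted, as is conventional for PDA saponin
#' calibration over a narrow dynamic range.
#'
#' @param points data.frame with columns `concentration` (mg/mL) and
#'   `peak_area`; at least 3 distinct concentrations.
#' @return A [calibration_fit()] with `model_kind = "linear"`,
#'   `conc_unit = "mg/mL"`.
#' @export
#' @examples
#' pts <- data.frame(concentration = c(0.1, 0.2, 0.3),
#'                   peak_area = 10175 * c(0.1, 0.2, 0.3) + 50838)
#' fit_linear(pts)
fit_linear <- function(points) {
  points <- .check_points(points)
  fit <- stats::lm(peak_area ~ concentration, data = points)
  cf <- stats::coef(fit)
  calibration_fit(
    model_kind = "linear",
    slope = unname(cf[["concentration"]]),
    intercept = unname(cf[["(Intercept)"]]),
    r = stats::cor(points$concentration, points$peak_area),
    # noise-free synthetic series are a designed use case: silence lm's
    # perfect-fit warning when extracting the residual SD
    residual_sd = suppressWarnings(summary(fit)$sigma),
    n_points = nrow(points),
    conc_unit = "mg/mL",
    valid_range = range(points$concentration)
  )
}

#' Fit a log-log (ELSD) calibration curve
#'
#' Least squares of `log10(peak_area)` on `log10(concentration)`, with
#' concentration converted from mg/mL to ug/mL before taking logs — the
#' ELSD convention that makes the fitted intercept comparable across the
#' field and underlies the `-3` back-conversion in the quantification
#' equations. Log base 10 throughout.
#'
#' @param points data.frame with columns `concentration` (mg/mL) and
#'   `peak_area` (> 0); at least 3 distinct concentrations.
#' @return A [calibration_fit()] with `model_kind = "loglog"`,
#'   `conc_unit = "ug/mL"` (slope/intercept live in log10 space;
#'   `valid_range` stays in mg/mL).
#' @export
fit_loglog <- function(points) {
  points <- .check_points(points)
  bad <- which(points$peak_area <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive peak area at point(s) %s: log-log fit undefined",
                 paste(bad, collapse = ", ")))
  }
  lx <- log10(1000 * points$concentration)
  ly <- log10(points$peak_area)
  fit <- stats::lm(ly ~ lx)
  cf <- stats::coef(fit)
  calibration_fit(
    model_kind = "loglog",
    slope = unname(cf[["lx"]]),
    intercept = unname(cf[["(Intercept)"]]),
    r = stats::cor(lx, ly),
    residual_sd = suppressWarnings(summary(fit)$sigma),
    n_points = nrow(points),
    conc_unit = "ug/mL",
    valid_range = range(points$concentration)
  )
}

#' Limits of detection and quantification from a calibration fit
#'
#' Residual-SD based limits in the ICH style: `LOD = 3.3 * s / a`,
#' `LOQ = 10 * s / a`, where `s` is the residual SD and `a` the slope of
#' the calibration fit, both taken in the domain the curve was fitted in.
#' For a linear (mg/mL) fit the result is already in mg/mL. For a log-log
#' fit the ratio `s/a` is formed in the log10 domain — residual SD in
#' log10-area units over the unitless log-log slope gives a concentration
#' spread expressed in the fit's ug/mL convention — and is then converted
#' to mg/mL. Both limits are exactly zero for a noise-free fit.
#'
#' @param fit A [calibration_fit()].
#' @param k_lod,k_loq Multipliers (defaults 3.3 and 10).
#' @return Named numeric vector `c(lod = ..., loq = ...)` in mg/mL.
#' @export
#' @examples
#' pts <- data.frame(concentration = 1:5, peak_area = 10 * (1:5) + rnorm(5))
#' lod_loq(fit_linear(pts))
lod_loq <- function(fit, k_lod = 3.3, k_loq = 10) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) stop("zero slope: LOD/LOQ undefined")
  ratio <- fit$residual_sd / fit$slope
  lod <- k_lod * ratio
  loq <- k_loq * ratio
  if (fit$model_kind == "loglog") {
    lod <- lod / 1000
    loq <- loq / 1000
  }
  c(lod = lod, loq = loq)
}

#' Predicted peak area from a calibration fit
#'
#' @param fit A [calibration_fit()].
#' @param conc_mg_ml Concentrations in mg/mL.
#' @return Peak areas on the detector's native scale.
#' @export
predict_area <- function(fit, conc_mg_ml) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$model_kind == "linear") {
    fit$slope * conc_mg_ml + fit$intercept
  } else {
    10^(fit$slope * log10(1000 * conc_mg_ml) + fit$intercept)
  }
}

#' Fit calibration curves for every (compound, detector, day) group
#'
#' Consumes a peak table (rows with `role == "calibration"` and
#' `known_conc_mg_per_ml` filled), fits a linear model for PDA rows and a
#' log-log model for ELSD rows per group, and returns the fits.
#'
#' @param peaks Peak-table data.frame (see [read_peak_table()] for the
#'   schema).
#' @return Named list of [calibration_fit()]s keyed
#'   `"compound|detector|day"`, with a `summary` attribute data.frame
#'   (one row per fit).
#' @export
calibrate_peak_table <- function(peaks) {
  cal <- peaks[peaks$role == "calibration", ]
  if (!nrow(cal)) stop("no calibration rows (role == 'calibration') found")
  if (any(is.na(cal$known_conc_mg_per_ml))) {
    stop("calibration rows must have known_conc_mg_per_ml")
  }
  keys <- unique(cal[, c("compound", "detector", "day")])
  fits <- vector("list", nrow(keys))
  names(fits) <- sprintf("%s|%s|%s", keys$compound, keys$detector, keys$day)
  for (i in seq_len(nrow(keys))) {
    sub <- cal[cal$compound == keys$compound[i] &
               cal$detector == keys$detector[i] &
               cal$day == keys$day[i], ]
    pts <- data.frame(concentration = sub$known_conc_mg_per_ml,
                      peak_area = sub$peak_area)
    fits[[i]] <- if (keys$detector[i] == "PDA") fit_linear(pts) else
      fit_loglog(pts)
  }
  summ <- cbind(keys, do.call(rbind, lapply(fits, function(f) {
    data.frame(model_kind = f$model_kind, slope = f$slope,
               intercept = f$intercept, r = f$r,
               residual_sd = f$residual_sd, n_points = f$n_points,
               range_low = f$valid_range[1], range_high = f$valid_range[2],
               stringsAsFactors = FALSE)
  })))
  rownames(summ) <- NULL
  attr(fits, "summary") <- summ
  fits
}

#' Look up one fit in a [calibrate_peak_table()] result
#'
#' @param fits Result of [calibrate_peak_table()].
#' @param compound,detector,day Group key.
#' @return The [calibration_fit()] for that group.
#' @export
get_fit <- function(fits, compound, detector, day = 1L) {
  key <- sprintf("%s|%s|%s", compound, detector, day)
  f <- fits[[key]]
  if (is.null(f)) stop(sprintf("no calibration fit for %s", key))
  f
}
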