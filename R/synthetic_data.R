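#' Detector response model
#'
#' Describes how a detector converts analyte concentration into an
#' integrated peak area. A PDA (photodiode array) detector responds
#' linearly, `area = slope * C + intercept` with `C` in mg/mL. An ELSD
#' (evaporative light-scattering detector) follows a power law, linear in
#' log-log coordinates: `log10(area) = slope * log10(C) + intercept` with
#' `C` in ug/mL (the conventional unit for ELSD calibration).
#'
#' Measurement noise is Gaussian in the domain in which the response is
#' linear: additive on the area for PDA, additive on log10(area) for ELSD
#' (i.e. multiplicative on the area itself, which keeps generated ELSD
#' areas strictly positive). `noise_rel` is a convenience parameterisation:
#' for PDA the per-point SD is `noise_rel` times the net response above
#' the intercept (`slope * C`) — the intercept acts as a fixed baseline
#' offset, and injection-to-injection variability scales with the peak
#' itself, not the baseline; for ELSD it is mapped to a log10-SD of
#' `noise_rel / log(10)`, which produces the same relative spread on the
#' area scale to first order.
#'
#' @param kind `"PDA"` or `"ELSD"`.
#' @param slope Response slope: area per (mg/mL) for PDA; unitless
#'   log-log slope for ELSD. Must be > 0.
#' @param intercept Response intercept: area units (PDA) or log10-area
#'   units (ELSD).
#' @param noise_sd Absolute noise SD: area units (PDA) or log10-area units
#'   (ELSD). Default 0.
#' @param noise_rel Relative noise as a fraction of signal; overrides
#'   `noise_sd` when non-zero.
#' @return An object of class `detector_model`.
#' @export
#' @examples
#' m <- detector_model("PDA", slope = 10175, intercept = 50838)
#' response_area(m, 0.36)  # noise-free area at 0.36 mg/mL
detector_model <- function(kind = c("PDA", "ELSD"), slope, intercept,
                           noise_sd = 0, noise_rel = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(slope), length(slope) == 1L, slope > 0,
            is.numeric(intercept), length(intercept) == 1L,
            noise_sd >= 0, noise_rel >= 0)
  structure(
    list(kind = kind, slope = slope, intercept = intercept,
         noise_sd = noise_sd, noise_rel = noise_rel,
         conc_unit = if (kind == "PDA") "mg/mL" else "ug/mL"),
    class = "detector_model"
  )
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model %s> slope=%g intercept=%g noise_sd=%g noise_rel=%g (conc in %s)\n",
              x$kind, x$slope, x$intercept, x$noise_sd, x$noise_rel,
              x$conc_unit))
  invisible(x)
}

#' Noise-free detector response
#'
#' Evaluates the model's deterministic response at given concentrations.
#'
#' @param model A [detector_model()].
#' @param conc_mg_ml Concentrations in mg/mL (converted internally to
#'   ug/mL for ELSD).
#' @return Peak areas (detector units), always > 0 for ELSD.
#' @export
response_area <- function(model, conc_mg_ml) {
  stopifnot(inherits(model, "detector_model"))
  if (any(conc_mg_ml <= 0)) {
    stop("concentrations must be strictly positive")
  }
  if (model$kind == "PDA") {
    model$slope * conc_mg_ml + model$intercept
  } else {
    10^(model$slope * log10(1000 * conc_mg_ml) + model$intercept)
  }
}

#' Geometric dilution design for calibration standards
#'
#' The calibration series starts from a stock concentration C1 per
#' compound and is serially diluted with a constant factor (default 0.75)
#' for a fixed number of levels (default 6), giving C1 > C2 > ... > C6.
#'
#' @param c1_by_compound Named numeric vector of stock concentrations
#'   (mg/mL), one per compound.
#' @param dilution_factor Dilution factor in (0, 1). Default 0.75.
#' @param n_levels Number of levels (>= 2). Default 6.
#' @return An object of class `dilution_design`.
#' @export
#' @examples
#' d <- dilution_design(vg_c1())
#' make_dilution_series(d, "G-Rb1")
dilution_design <- function(c1_by_compound, dilution_factor = 0.75,
                            n_levels = 6L) {
  stopifnot(is.numeric(c1_by_compound), length(c1_by_compound) >= 1L,
            !is.null(names(c1_by_compound)), all(c1_by_compound > 0),
            dilution_factor > 0, dilution_factor < 1 || dilution_factor == 1,
            n_levels >= 2L)
  structure(
    list(c1 = c1_by_compound, factor = dilution_factor,
         n_levels = as.integer(n_levels)),
    class = "dilution_design"
  )
}

#' Concentration levels of a dilution series
#'
#' @param design A [dilution_design()].
#' @param compound Compound identifier present in the design.
#' @return Numeric vector of concentrations (mg/mL), descending:
#'   level i equals `c1 * factor^(i-1)`.
#' @export
make_dilution_series <- function(design, compound) {
  stopifnot(inherits(design, "dilution_design"))
  if (!compound %in% names(design$c1)) {
    stop(sprintf("unknown compound '%s' in dilution design", compound))
  }
  design$c1[[compound]] * design$factor^(seq_len(design$n_levels) - 1)
}

#' Simulate a calibration series
#'
#' Generates peak areas at the supplied concentrations from a detector
#' model, with noise in the model's native domain (see
#' [detector_model()]). With the same seed the output is identical.
#'
#' @param concentrations Concentrations in mg/mL, all > 0.
#' @param model A [detector_model()].
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param day,replicate Tags copied into the output.
#' @return A data.frame (one row per level) with columns `level_index`,
#'   `concentration` (mg/mL), `peak_area`, `detector`, `day`, `replicate`.
#' @export
simulate_calibration <- function(concentrations, model, seed = NULL,
                                 day = 1L, replicate = 1L) {
  stopifnot(inherits(model, "detector_model"))
  if (any(concentrations <= 0)) {
    stop("concentrations must be strictly positive")
  }
  if (!is.null(seed)) set.seed(seed)
  base <- response_area(model, concentrations)
  area <- .apply_noise(base, model)
  data.frame(
    level_index = seq_along(concentrations),
    concentration = concentrations,
    peak_area = area,
    detector = model$kind,
    day = day,
    replicate = replicate,
    stringsAsFactors = FALSE
  )
}

# Draw noisy areas around the noise-free response, in the model's native
# noise domain. `base` are noise-free areas.
.apply_noise <- function(base, model) {
  n <- length(base)
  if (model$kind == "PDA") {
    sd_i <- if (model$noise_rel > 0)
      model$noise_rel * pmax(base - model$intercept, 0) else
      rep(model$noise_sd, n)
    base + stats::rnorm(n, 0, sd_i)
  } else {
    sd_log <- if (model$noise_rel > 0) model$noise_rel / log(10) else
      model$noise_sd
    10^(log10(base) + stats::rnorm(n, 0, sd_log))
  }
}

#' Measurement scenario for synthetic samples
#'
#' Bundles the ground truth used to generate synthetic sample
#' measurements: the true dry-weight contents, the sample preparation
#' parameters (mass extracted into a fixed final volume), an optional
#' multiplicative day-to-day response drift per compound, and the spike
#' levels for recovery studies.
#'
#' The content-to-concentration mapping inverts `H(%) = V * C / m * 100`:
#' a compound at true content `H` percent in `m` mg of powder extracted
#' into `V` mL gives a solution concentration `C = H * m / (100 * V)`
#' mg/mL.
#'
#' @param true_contents Named numeric vector, percent dry weight per
#'   compound.
#' @param sample_mass Dry sample mass m in mg (default 100).
#' @param final_volume Final solution volume V in mL (default 5).
#' @param day_drift Either `NULL` (no drift) or a named list mapping day
#'   (as character) to a named numeric vector of per-compound
#'   multiplicative response factors (all > 0).
#' @param spike_levels Spike levels as fractions of the nominal content
#'   (default `c(0.8, 1.0, 1.2)`).
#' @param seed Integer seed controlling all randomness downstream.
#' @return An object of class `qams_scenario`.
#' @export
qams_scenario <- function(true_contents, sample_mass = 100,
                          final_volume = 5, day_drift = NULL,
                          spike_levels = c(0.8, 1.0, 1.2), seed = 1L) {
  stopifnot(is.numeric(true_contents), !is.null(names(true_contents)),
            all(true_contents > 0), sample_mass > 0, final_volume > 0,
            all(spike_levels >= 0))
  if (!is.null(day_drift)) {
    ok <- vapply(day_drift, function(v) is.numeric(v) && all(v > 0),
                 logical(1))
    if (!all(ok)) stop("day_drift factors must all be > 0")
  }
  structure(
    list(true_contents = true_contents, sample_mass = sample_mass,
         final_volume = final_volume, day_drift = day_drift,
         spike_levels = spike_levels, seed = as.integer(seed)),
    class = "qams_scenario"
  )
}

# Drift factor for (day, compound); 1 when no drift is configured.
.drift_factor <- function(scenario, day, compound) {
  dd <- scenario$day_drift
  if (is.null(dd)) return(1)
  v <- dd[[as.character(day)]]
  if (is.null(v) || !compound %in% names(v)) return(1)
  v[[compound]]
}

#' True solution concentration implied by a scenario
#'
#' @param scenario A [qams_scenario()].
#' @param compound Compound identifier.
#' @return Concentration in mg/mL: `H * m / (100 * V)`.
#' @export
true_concentration <- function(scenario, compound) {
  stopifnot(inherits(scenario, "qams_scenario"))
  if (!compound %in% names(scenario$true_contents)) {
    stop(sprintf("no true content configured for '%s'", compound))
  }
  scenario$true_contents[[compound]] * scenario$sample_mass /
    (100 * scenario$final_volume)
}

#' Simulate replicate sample measurements
#'
#' Emits one peak-table row per compound per replicate for a sample whose
#' true contents are given by the scenario. The day-drift factor
#' multiplies the noise-free response; noise is then applied in the
#' detector's native domain.
#'
#' @param scenario A [qams_scenario()].
#' @param models Named list of [detector_model()]s keyed by compound (all
#'   of one detector kind).
#' @param n_replicates Number of replicate preparations (default 3).
#' @param day,lab,sample_id Tags copied into the output.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return Peak-table data.frame with columns `sample_id`, `compound`,
#'   `detector`, `day`, `lab`, `replicate`, `known_conc_mg_per_ml`
#'   (`NA` for unknowns), `peak_area`, `role = "sample"`.
#' @export
simulate_sample_set <- function(scenario, models, n_replicates = 3L,
                                day = 1L, lab = "lab1", sample_id = "S1",
                                seed = NULL) {
  stopifnot(inherits(scenario, "qams_scenario"), is.list(models))
  compounds <- names(scenario$true_contents)
  missing <- setdiff(compounds, names(models))
  if (length(missing)) {
    stop(sprintf("no detector model for compound(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(compounds, function(cp) {
    model <- models[[cp]]
    conc <- true_concentration(scenario, cp)
    base <- response_area(model, conc) * .drift_factor(scenario, day, cp)
    area <- .apply_noise(rep(base, n_replicates), model)
    data.frame(
      sample_id = sample_id, compound = cp, detector = model$kind,
      day = day, lab = lab, replicate = seq_len(n_replicates),
      known_conc_mg_per_ml = NA_real_, peak_area = area,
      role = "sample", stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Build a spiked-recovery measurement set
#'
#' Simulates the accuracy (spiked standard) design: to a base sample with
#' known (quantified) contents, reference standard is added at the
#' scenario's spike levels (default 80/100/120% of the nominal content),
#' with `n_prep` independent preparations per level — 9 spiked records
#' per compound under the defaults.
#'
#' @param scenario A [qams_scenario()]; its `true_contents` act as the
#'   base sample's contents.
#' @param models Named list of [detector_model()]s keyed by compound.
#' @param n_prep Preparations per spike level (default 3).
#' @param day,lab Tags copied into the output.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A list with `peaks` (peak-table rows, `role = "spike"`) and
#'   `design` (data.frame `sample_id`, `compound`, `spike_level`,
#'   `added_content_pct`). A spike level of zero is rejected: recovery is
#'   undefined with nothing added.
#' @export
make_spike_design <- function(scenario, models, n_prep = 3L,
                              day = 1L, lab = "lab1", seed = NULL) {
  stopifnot(inherits(scenario, "qams_scenario"))
  if (any(scenario$spike_levels <= 0)) {
    stop("spike levels must be > 0: zero added amount leaves recovery undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  compounds <- names(scenario$true_contents)
  peaks <- list(); design <- list()
  for (cp in compounds) {
    model <- models[[cp]]
    if (is.null(model)) stop(sprintf("no detector model for '%s'", cp))
    base_h <- scenario$true_contents[[cp]]
    for (li in seq_along(scenario$spike_levels)) {
      lev <- scenario$spike_levels[[li]]
      added_h <- lev * base_h
      spiked_conc <- (base_h + added_h) * scenario$sample_mass /
        (100 * scenario$final_volume)
      for (prep in seq_len(n_prep)) {
        sid <- sprintf("spike_L%03d_p%d", round(100 * lev), prep)
        base_area <- response_area(model, spiked_conc) *
          .drift_factor(scenario, day, cp)
        area <- .apply_noise(base_area, model)
        peaks[[length(peaks) + 1L]] <- data.frame(
          sample_id = sid, compound = cp, detector = model$kind,
          day = day, lab = lab, replicate = prep,
          known_conc_mg_per_ml = NA_real_, peak_area = area,
          role = "spike", stringsAsFactors = FALSE
        )
        design[[length(design) + 1L]] <- data.frame(
          sample_id = sid, compound = cp, spike_level = lev,
          added_content_pct = added_h, stringsAsFactors = FALSE
        )
      }
    }
  }
  list(peaks = do.call(rbind, peaks), design = do.call(rbind, design))
}

#' Simulate a full calibration peak table
#'
#' Convenience wrapper generating calibration rows (role =
#' `"calibration"`) for every compound in a dilution design across one or
#' more days, using one detector-model list.
#'
#' @param design A [dilution_design()].
#' @param models Named list of [detector_model()]s keyed by compound.
#' @param days Integer vector of day tags (default 1).
#' @param lab Lab tag.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return Peak-table data.frame (schema as [simulate_sample_set()]) with
#'   `known_conc_mg_per_ml` filled in.
#' @export
simulate_calibration_table <- function(design, models, days = 1L,
                                       lab = "lab1", seed = NULL) {
  stopifnot(inherits(design, "dilution_design"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (day in days) {
    for (cp in names(design$c1)) {
      model <- models[[cp]]
      if (is.null(model)) stop(sprintf("no detector model for '%s'", cp))
      conc <- make_dilution_series(design, cp)
      ser <- simulate_calibration(conc, model, seed = NULL, day = day)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("cal_%s_d%s", cp, day), compound = cp,
        detector = model$kind, day = day, lab = lab,
        replicate = ser$level_index,
        known_conc_mg_per_ml = ser$concentration,
        peak_area = ser$peak_area, role = "calibration",
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
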