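PEAK_TABLE_COLUMNS <- c("sample_id", "compound", "detector", "day", "lab",
                        "replicate", "known_conc_mg_per_ml", "peak_area",
                        "role")

#' Read a peak table CSV
#'
#' Validates the schema on the way in: all columns present, ELSD areas
#' strictly positive, no duplicate (sample_id, compound, detector,
#' replicate, day, lab) keys, roles from the known vocabulary. Errors
#' name the offending rows.
#'
#' @param path CSV path (comma-separated, UTF-8, header row, decimal
#'   point).
#' @return Peak-table data.frame.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PEAK_TABLE_COLUMNS, names(df))
  if (length(missing)) {
    stop(sprintf("peak table %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  bad_role <- which(!df$role %in% c("calibration", "sample", "spike", "blank"))
  if (length(bad_role)) {
    stop(sprintf("unknown role at row(s) %s",
                 paste(bad_role, collapse = ", ")))
  }
  bad_area <- which(df$detector == "ELSD" & df$peak_area <= 0)
  if (length(bad_area)) {
    stop(sprintf("nonpositive ELSD peak area at row(s) %s",
                 paste(bad_area, collapse = ", ")))
  }
  key <- do.call(paste, c(df[, c("sample_id", "compound", "detector",
                                 "replicate", "day", "lab")], sep = "|"))
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate measurement key at row(s) %s",
                 paste(dup, collapse = ", ")))
  }
  df
}

#' Write a peak table CSV
#'
#' @param peaks Peak-table data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  stopifnot(all(PEAK_TABLE_COLUMNS %in% names(peaks)))
  utils::write.csv(peaks[, PEAK_TABLE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write calibration fits to JSON
#'
#' @param fits Result of [calibrate_peak_table()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(fits, path) {
  jsonlite::write_json(
    lapply(fits, function(f) unclass(f)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read calibration fits from JSON
#'
#' @param path JSON path written by [write_calibration_json()].
#' @return Named list of [calibration_fit()] objects.
#' @export
read_calibration_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fits <- lapply(raw, function(f) {
    calibration_fit(f$model_kind, f$slope, f$intercept, f$r,
                    f$residual_sd, f$n_points, f$conc_unit,
                    as.numeric(f$valid_range))
  })
  names(fits) <- names(raw)
  fits
}

#' Run configuration for the QAMS pipeline
#'
#' Collects everything the simulate-calibrate-factors-quantify-validate
#' chain needs. Standard-purity correction (multiplying nominal standard
#' concentrations by the certified purity) is off by default.
#'
#' @param compounds Character vector of compound ids (default the five
#'   VG saponins).
#' @param c1 Named numeric stock concentrations mg/mL (default
#'   [vg_c1()]).
#' @param dilution_factor,n_levels Dilution design (defaults 0.75, 6).
#' @param detectors Detectors to run (`"PDA"`, `"ELSD"` or both).
#' @param markers List keyed by detector of analyte -> marker maps
#'   (default [vg_marker_assignment()] restricted to `compounds`).
#' @param true_contents Named numeric percent dry-weight contents.
#' @param noise_rel Relative measurement noise fraction (default 0.02).
#' @param day_drift Optional drift spec (see [qams_scenario()]).
#' @param volume_ml,mass_mg Sample prep parameters (defaults 5 mL,
#'   100 mg).
#' @param n_replicates Replicate sample preparations (default 6).
#' @param days Calibration days (default 1:3).
#' @param fx_provenance `"intra_day"` or `"inter_day_mean"`.
#' @param purity_correction Apply certified purities to standard
#'   concentrations (default `FALSE`).
#' @param seed Integer seed (mandatory).
#' @return Object of class `qams_config`.
#' @export
qams_config <- function(compounds = vg_compounds()$compound,
                        c1 = vg_c1(),
                        dilution_factor = 0.75, n_levels = 6L,
                        detectors = c("PDA", "ELSD"),
                        markers = NULL,
                        true_contents = c("G-Rb1" = 1.46, "G-Rd" = 0.96,
                                          "G-Rg1" = 3.96, "M-R2" = 5.51,
                                          "V-R2" = 2.67),
                        noise_rel = 0.02,
                        day_drift = NULL,
                        volume_ml = 5, mass_mg = 100,
                        n_replicates = 6L, days = 1:3,
                        fx_provenance = c("intra_day", "inter_day_mean"),
                        purity_correction = FALSE,
                        seed) {
  fx_provenance <- match.arg(fx_provenance)
  stopifnot(!missing(seed), is.numeric(seed))
  detectors <- match.arg(detectors, several.ok = TRUE)
  if (is.null(markers)) {
    markers <- lapply(stats::setNames(detectors, detectors), function(d) {
      mk <- vg_marker_assignment(d)
      mk[names(mk) %in% compounds]
    })
  }
  for (d in names(markers)) {
    mk_vals <- markers[[d]]
    if (!all(mk_vals %in% names(mk_vals))) {
      stop("every marker must itself be an analyte in the assignment")
    }
    if (!all(names(mk_vals) %in% compounds)) {
      stop("marker assignment names an unknown compound")
    }
  }
  structure(
    list(compounds = compounds, c1 = c1,
         dilution_factor = dilution_factor, n_levels = as.integer(n_levels),
         detectors = detectors, markers = markers,
         true_contents = true_contents, noise_rel = noise_rel,
         day_drift = day_drift, volume_ml = volume_ml, mass_mg = mass_mg,
         n_replicates = as.integer(n_replicates), days = days,
         fx_provenance = fx_provenance,
         purity_correction = purity_correction, seed = as.integer(seed)),
    class = "qams_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [qams_config()]
#'   arguments; `seed` is mandatory.
#' @return A `qams_config`.
#' @export
read_qams_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed")
  for (nm in c("c1", "true_contents")) {
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  }
  if (!is.null(y$markers)) y$markers <- lapply(y$markers, unlist)
  do.call(qams_config, y)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; changes iff the
#' configuration content changes.
#'
#' @param config A `qams_config`.
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Apply certified purity to nominal standard concentrations
#'
#' @param c1 Named nominal concentrations (mg/mL).
#' @param purities Named purities in (0, 1] (default from
#'   [vg_compounds()]).
#' @return Effective concentrations: nominal x purity.
#' @export
purity_correct <- function(c1, purities = NULL) {
  if (is.null(purities)) {
    cmp <- vg_compounds()
    purities <- stats::setNames(cmp$purity, cmp$compound)
  }
  stopifnot(all(names(c1) %in% names(purities)),
            all(purities > 0), all(purities <= 1))
  c1 * purities[names(c1)]
}

#' Run the full QAMS pipeline on a synthetic scenario
#'
#' Chains the five stages — simulate, calibrate, derive conversion
#' factors, quantify, validate — for every configured detector.
#' Deterministic given the config seed: the same config yields the same
#' artifact bundle.
#'
#' @param config A [qams_config()].
#' @param out_dir If non-NULL, artifacts (peak table CSV, calibration
#'   JSON, F_x CSV, quantification CSV, comparison CSV, run log JSON)
#'   are written there.
#' @return List with elements `peaks`, `fits`, `factors`, `quant`,
#'   `comparison`, `precision`, `config_hash` (and `paths` when
#'   `out_dir` is given).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "qams_config"))
  set.seed(config$seed)
  c1 <- config$c1[config$compounds]
  if (config$purity_correction) c1 <- purity_correct(c1)

  peaks_all <- list(); quant_all <- list(); fits_all <- list()
  factors_all <- list()
  for (det in config$detectors) {
    models <- vg_detector_models(det, noise_rel = config$noise_rel)
    quantifiable <- names(config$markers[[det]])
    models <- models[intersect(names(models), config$compounds)]
    design <- dilution_design(c1[names(models)], config$dilution_factor,
                              config$n_levels)
    peaks <- simulate_calibration_table(design, models, days = config$days)
    scen <- qams_scenario(
      true_contents = config$true_contents[quantifiable],
      sample_mass = config$mass_mg, final_volume = config$volume_ml,
      day_drift = config$day_drift, seed = config$seed)
    samp <- simulate_sample_set(scen, models,
                                n_replicates = config$n_replicates,
                                day = config$days[1])
    peaks <- rbind(peaks, samp)
    fits <- calibrate_peak_table(peaks)
    factors <- build_fx_table(fits, peaks,
                              markers = config$markers[det],
                              days = config$days,
                              provenance = config$fx_provenance)
    quant <- quantify_samples(peaks, fits, factors, config$markers[det],
                              config$volume_ml, config$mass_mg,
                              fit_day = config$days[1])
    peaks_all[[det]] <- peaks
    fits_all <- c(fits_all, fits)
    factors_all <- c(factors_all, factors)
    quant_all[[det]] <- quant
  }
  peaks <- do.call(rbind, peaks_all)
  quant <- do.call(rbind, quant_all)
  rownames(peaks) <- rownames(quant) <- NULL
  comparison <- compare_methods(quant[quant$role == "sample", ])
  precision <- precision_summary(quant[quant$role == "sample", ])
  bundle <- list(peaks = peaks, fits = fits_all, factors = factors_all,
                 quant = quant, comparison = comparison,
                 precision = precision, config_hash = config_hash(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      peaks = file.path(out_dir, "peak_table.csv"),
      calibration = file.path(out_dir, "calibration.json"),
      fx = file.path(out_dir, "conversion_factors.csv"),
      quant = file.path(out_dir, "quantification.csv"),
      comparison = file.path(out_dir, "method_comparison.csv"),
      log = file.path(out_dir, "run_log.json")
    )
    write_peak_table(peaks, paths$peaks)
    write_calibration_json(fits_all, paths$calibration)
    utils::write.csv(fx_table_df(factors_all), paths$fx, row.names = FALSE)
    utils::write.csv(quant, paths$quant, row.names = FALSE)
    utils::write.csv(comparison, paths$comparison, row.names = FALSE)
    jsonlite::write_json(
      list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
           package_version = as.character(utils::packageVersion("qamsvg")),
           config_hash = bundle$config_hash),
      paths$log, auto_unbox = TRUE)
    bundle$paths <- paths
  }
  bundle
}
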