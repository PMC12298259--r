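#' Standard method difference between ESM and QAMS contents
#'
#' `SMD(%) = |H_ESM - H_QAMS| / H_ESM * 100`. An SMD at or below 5.00%
#' is the conventional criterion for "no significant difference" between
#' the single-marker result and the external-standard result.
#'
#' @param h_esm Content by the external-standard method (%), > 0.
#' @param h_qams Content by the single-marker method (%).
#' @return SMD in percent (>= 0). Vectorised over both arguments.
#' @export
#' @examples
#' smd(5.71, 4.13)  # 27.67
smd <- function(h_esm, h_qams) {
  if (any(h_esm <= 0)) stop("ESM content must be positive")
  abs(h_esm - h_qams) / h_esm * 100
}

#' Relative standard deviation
#'
#' Sample SD over mean, in percent.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return RSD in percent.
#' @export
#' @examples
#' rsd(c(2, 4))  # 47.14
rsd <- function(values) {
  if (length(values) < 2L) stop("RSD requires at least 2 values")
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean")
  stats::sd(values) / m * 100
}

#' Spiked recovery
#'
#' `(found_spiked - found_base) / added * 100`: the fraction of the
#' added amount recovered by the quantification, in percent. All three
#' arguments share a unit (content % or amount).
#'
#' @param found_spiked Content found in the spiked sample.
#' @param found_base Content found in the unspiked base sample.
#' @param added Amount added (> 0).
#' @return Recovery in percent. Vectorised.
#' @export
recovery <- function(found_spiked, found_base, added) {
  if (any(added <= 0)) stop("added amount must be positive")
  (found_spiked - found_base) / added * 100
}

#' Precision summary: intra-day, inter-day and inter-laboratory RSDs
#'
#' Computes RSDs of replicate contents grouped by (compound, detector,
#' method): intra-day RSD within each (day, lab) cell; inter-day RSD
#' across the days of one lab; inter-laboratory RSD across labs. The
#' pooled convention (default) computes the across-group RSDs on all
#' individual replicate values pooled together; `pooled = FALSE`
#' computes them on the per-cell means instead.
#'
#' @param quant Long quantification data.frame (as returned by
#'   [quantify_samples()]) with columns `compound`, `detector`, `method`,
#'   `day`, `lab`, `content_pct`.
#' @param pooled Use pooled individual values for inter-day/inter-lab
#'   RSDs (default `TRUE`).
#' @return data.frame with columns `compound`, `detector`, `method`,
#'   `grouping` (`intra_day` / `inter_day` / `inter_laboratory`), `day`,
#'   `lab`, `n`, `rsd_pct`.
#' @export
precision_summary <- function(quant, pooled = TRUE) {
  need <- c("compound", "detector", "method", "day", "lab", "content_pct")
  stopifnot(all(need %in% names(quant)))
  if (!nrow(quant)) stop("empty quantification table")
  out <- list()
  keys <- unique(quant[, c("compound", "detector", "method")])
  for (i in seq_len(nrow(keys))) {
    sub <- quant[quant$compound == keys$compound[i] &
                 quant$detector == keys$detector[i] &
                 quant$method == keys$method[i], ]
    cells <- unique(sub[, c("day", "lab")])
    for (j in seq_len(nrow(cells))) {
      v <- sub$content_pct[sub$day == cells$day[j] & sub$lab == cells$lab[j]]
      out[[length(out) + 1L]] <- data.frame(
        keys[i, ], grouping = "intra_day", day = as.character(cells$day[j]),
        lab = cells$lab[j], n = length(v), rsd_pct = rsd(v),
        stringsAsFactors = FALSE)
    }
    for (lb in unique(sub$lab)) {
      sl <- sub[sub$lab == lb, ]
      if (length(unique(sl$day)) > 1L) {
        v <- if (pooled) sl$content_pct else
          tapply(sl$content_pct, sl$day, mean)
        out[[length(out) + 1L]] <- data.frame(
          keys[i, ], grouping = "inter_day", day = "all", lab = lb,
          n = length(v), rsd_pct = rsd(as.numeric(v)),
          stringsAsFactors = FALSE)
      }
    }
    if (length(unique(sub$lab)) > 1L) {
      v <- if (pooled) sub$content_pct else
        tapply(sub$content_pct, sub$lab, mean)
      out[[length(out) + 1L]] <- data.frame(
        keys[i, ], grouping = "inter_laboratory", day = "all", lab = "all",
        n = length(v), rsd_pct = rsd(as.numeric(v)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare QAMS variants against the ESM baseline
#'
#' For each (compound, detector) group, pairs every QAMS replicate
#' result with the matching ESM replicate (same sample, replicate, day,
#' lab), computes the per-replicate SMD, and reports mean content and
#' mean/SD of the SMD per QAMS variant together with the pass flag of
#' the agreement rule. Computing SMD per replicate and then averaging is
#' deliberate: it is not identical to the SMD of the mean contents.
#'
#' @param quant Long quantification data.frame from
#'   [quantify_samples()]; must contain an `ESM` method and at least one
#'   QAMS variant per group.
#' @param rule Agreement threshold in percent (default 5).
#' @return data.frame with one row per (compound, detector, QAMS
#'   variant): mean/SD of ESM and QAMS contents, `smd_mean`, `smd_sd`,
#'   `n`, `pass` (`smd_mean <= rule`).
#' @export
compare_methods <- function(quant, rule = 5.00) {
  stopifnot(all(c("compound", "detector", "method", "content_pct")
                %in% names(quant)))
  keycols <- intersect(c("sample_id", "replicate", "day", "lab"),
                       names(quant))
  out <- list()
  groups <- unique(quant[, c("compound", "detector")])
  for (i in seq_len(nrow(groups))) {
    sub <- quant[quant$compound == groups$compound[i] &
                 quant$detector == groups$detector[i], ]
    esm <- sub[sub$method == "ESM", ]
    if (!nrow(esm)) {
      stop(sprintf("no ESM baseline for %s on %s",
                   groups$compound[i], groups$detector[i]))
    }
    for (mth in setdiff(unique(sub$method), "ESM")) {
      qm <- sub[sub$method == mth, ]
      merged <- merge(esm, qm, by = keycols,
                      suffixes = c("_esm", "_qams"))
      if (!nrow(merged)) next
      s <- smd(merged$content_pct_esm, merged$content_pct_qams)
      out[[length(out) + 1L]] <- data.frame(
        compound = groups$compound[i], detector = groups$detector[i],
        method = mth, marker = qm$marker[1],
        h_esm_mean = mean(merged$content_pct_esm),
        h_esm_sd = stats::sd(merged$content_pct_esm),
        h_qams_mean = mean(merged$content_pct_qams),
        h_qams_sd = stats::sd(merged$content_pct_qams),
        smd_mean = mean(s),
        smd_sd = if (length(s) > 1L) stats::sd(s) else 0,
        n = length(s),
        pass = mean(s) <= rule,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recovery summary for a spiked design
#'
#' Joins quantified spike results with the spike design, pairs each
#' spiked record with the mean base-sample content of the same compound,
#' detector and method, and computes per-record recoveries.
#'
#' @param quant_spike Quantification rows for the spiked records
#'   (`role == "spike"` in [quantify_samples()] output).
#' @param quant_base Quantification rows for the unspiked base sample.
#' @param design Spike design data.frame from [make_spike_design()]
#'   (`sample_id`, `compound`, `spike_level`, `added_content_pct`).
#' @return data.frame with per-record recoveries and the grouping tags.
#' @export
recovery_summary <- function(quant_spike, quant_base, design) {
  merged <- merge(quant_spike, design, by = c("sample_id", "compound"))
  if (!nrow(merged)) stop("spike results do not match the spike design")
  base_mean <- stats::aggregate(
    content_pct ~ compound + detector + method, data = quant_base, mean)
  names(base_mean)[names(base_mean) == "content_pct"] <- "base_content"
  merged <- merge(merged, base_mean, by = c("compound", "detector", "method"))
  merged$recovery_pct <- recovery(merged$content_pct, merged$base_content,
                                  merged$added_content_pct)
  merged[order(merged$compound, merged$method, merged$spike_level,
               merged$replicate),
         c("compound", "detector", "method", "marker", "spike_level",
           "replicate", "added_content_pct", "base_content", "content_pct",
           "recovery_pct")]
}
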