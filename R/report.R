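#' Two-group cohort comparison report
#'
#' Mirrors the published table layout: per feature, the per-group median
#' and range of the per-patient medians plus the two-sided Mann-Whitney p,
#' followed by Spearman correlations of every feature against the
#' peripheral leukocyte count. Raw p-values, no multiple-testing
#' correction (reported as such).
#'
#' @param features per-nucleus feature data.frame (with `patient_id`)
#' @param patients patient table with `patient_id`, the grouping column,
#'   and `leukocyte_count`
#' @param grouping name of the binary grouping column (exactly 2 levels)
#' @param min_nuclei minimum nuclei per patient for aggregation
#' @return list of class `cohort_report` with `comparison` and
#'   `correlations` data.frames
#' @export
cohort_report <- function(features, patients, grouping = "flt3_itd",
                          min_nuclei = 100L) {
  stopifnot(is.data.frame(patients), "patient_id" %in% names(patients),
            grouping %in% names(patients))
  med <- aggregate_patient(features, min_nuclei)
  orphans <- setdiff(med$patient_id, patients$patient_id)
  if (length(orphans)) {
    stop("feature table has patients missing from the patient table: ",
         paste(orphans, collapse = ", "))
  }
  d <- merge(med, patients, by = "patient_id")
  glev <- sort(unique(d[[grouping]]))
  if (length(glev) != 2L) {
    stop("grouping '", grouping, "' must have exactly 2 levels, found ",
         length(glev))
  }
  feat_cols <- setdiff(names(med), "patient_id")
  rows <- c(feat_cols,
            if ("leukocyte_count" %in% names(patients)) "leukocyte_count")
  comparison <- do.call(rbind, lapply(rows, function(f) {
    v1 <- d[[f]][d[[grouping]] == glev[1]]
    v2 <- d[[f]][d[[grouping]] == glev[2]]
    mw <- mann_whitney(v1, v2)
    data.frame(
      feature = f,
      median_g1 = stats::median(v1),
      range_g1 = sprintf("%.4g - %.4g", min(v1), max(v1)),
      median_g2 = stats::median(v2),
      range_g2 = sprintf("%.4g - %.4g", min(v2), max(v2)),
      p = mw$p_value,
      stringsAsFactors = FALSE)
  }))
  correlations <- NULL
  if ("leukocyte_count" %in% names(patients)) {
    correlations <- do.call(rbind, lapply(feat_cols, function(f) {
      sp <- spearman(d[[f]], d$leukocyte_count)
      data.frame(feature = f, rho = sp$statistic, p = sp$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(comparison = comparison, correlations = correlations,
                 grouping = grouping, groups = glev),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Group comparison by '%s' (%s vs %s), Mann-Whitney p:\n",
              x$grouping, x$groups[1], x$groups[2]))
  print(x$comparison, row.names = FALSE, digits = 4)
  if (!is.null(x$correlations)) {
    cat("\nSpearman correlation with leukocyte count:\n")
    print(x$correlations, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
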