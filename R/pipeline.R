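#' Extract the ten texture/morphometry features of one nucleus
#'
#' Geometric morphometry (area, form factor, gray mean/SD), the four GLCM
#' features, and the blanket fractal dimension with its quality of
#' fractality.
#'
#' @param n a [nucleus_image()]
#' @param eps_max blanket dilation range
#' @param glcm_base entropy logarithm base
#' @return named numeric vector of the 10 features
#' @export
nucleus_features <- function(n, eps_max = 15L, glcm_base = 2) {
  c(morphometry_features(n, largest_component = TRUE),
    glcm_features(compute_glcm(n), base = glcm_base),
    fractal_features(n, eps_max = eps_max))
}

feature_names <- c("area_um2", "form_factor", "mean_gray", "sd_gray",
                   "entropy", "contrast", "local_homogeneity",
                   "cluster_prominence", "fd", "r2")

#' Compute the per-nucleus feature table from a manifest
#'
#' Reads the manifest CSV written by [write_cohort()] (columns
#' `patient_id, nucleus_id, image_path, mask_path`, paths relative to the
#' manifest), computes the 10 features per nucleus and writes one CSV row
#' per nucleus. Deterministic: rerunning on the same inputs is
#' byte-identical. With `resume = TRUE`, nuclei already present in `out`
#' are skipped. Unreadable images are logged; unless `keep_going = TRUE`
#' the first failure aborts, otherwise failures are reported at the end
#' via an error (intact rows are still written).
#'
#' @param manifest path to the manifest CSV
#' @param calibration micrometres per pixel edge
#' @param out output CSV path
#' @param eps_max,glcm_base feature options
#' @param resume skip nuclei already in `out`
#' @param keep_going process all rows before failing on errors
#' @param quiet suppress progress messages
#' @return invisibly, the feature data.frame
#' @export
run_features <- function(manifest, calibration = 0.1, out,
                         eps_max = 15L, glcm_base = 2,
                         resume = FALSE, keep_going = FALSE, quiet = TRUE) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("patient_id", "nucleus_id", "image_path", "mask_path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base_dir <- dirname(manifest)
  done <- NULL
  if (resume && file.exists(out)) {
    done <- utils::read.csv(out, stringsAsFactors = FALSE)
  }
  rows <- vector("list", nrow(man))
  failures <- character(0)
  for (k in seq_len(nrow(man))) {
    pid <- man$patient_id[k]; nid <- man$nucleus_id[k]
    if (!is.null(done) &&
        any(done$patient_id == pid & done$nucleus_id == nid)) {
      rows[[k]] <- done[done$patient_id == pid & done$nucleus_id == nid, ][1, ]
      next
    }
    res <- tryCatch({
      n <- load_nucleus(file.path(base_dir, man$image_path[k]),
                        file.path(base_dir, man$mask_path[k]),
                        calibration, pid, nid)
      fv <- nucleus_features(n, eps_max = eps_max, glcm_base = glcm_base)
      cbind(data.frame(patient_id = pid, nucleus_id = nid,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(fv)))
    }, error = function(e) {
      message("FAILED ", pid, "/", nid, ": ", conditionMessage(e))
      conditionMessage(e)
    })
    if (is.character(res)) {
      failures <- c(failures, paste0(pid, "/", nid, ": ", res))
      if (!keep_going) {
        stop("feature extraction failed for ", pid, "/", nid, ": ", res)
      }
    } else {
      rows[[k]] <- res
    }
    if (!quiet && k %% 100 == 0) message("processed ", k, "/", nrow(man))
  }
  feats <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  utils::write.csv(feats, out, row.names = FALSE)
  if (length(failures)) {
    stop(length(failures), " nucle", if (length(failures) == 1) "us" else "i",
         " failed (other rows written to ", out, "):\n  ",
         paste(failures, collapse = "\n  "))
  }
  invisible(feats)
}

#' Run the cohort statistics stage
#'
#' Aggregates nuclei to patients, then writes the group-comparison CSV,
#' the leukocyte-correlation CSV, the Cox CSV (univariate and stratified,
#' one row per feature and clinical covariate), and a run-metadata JSON
#' (config echo, package version, seed).
#'
#' @param features_csv per-nucleus feature CSV from [run_features()]
#' @param patients_csv patient table CSV
#' @param out_dir output directory
#' @param grouping binary grouping column for the comparison table
#' @param strata stratification column for the stratified Cox pass
#' @param min_nuclei minimum nuclei per patient
#' @param ci_level confidence level for exact binomial CIs
#' @param seed seed echoed into the metadata (the stage itself is
#'   deterministic)
#' @return invisibly, a list with the three report data.frames
#' @export
run_stats <- function(features_csv, patients_csv, out_dir,
                      grouping = "flt3_itd", strata = "flt3_itd",
                      min_nuclei = 100L, ci_level = 0.95, seed = NA) {
  feats <- utils::read.csv(features_csv, stringsAsFactors = FALSE)
  patients <- utils::read.csv(patients_csv, stringsAsFactors = FALSE)
  if (!nrow(patients)) stop("patients table is empty")
  orphans <- setdiff(unique(feats$patient_id), patients$patient_id)
  if (length(orphans)) {
    stop("patients present in features but missing from ", patients_csv,
         ": ", paste(orphans, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rep <- cohort_report(feats, patients, grouping, min_nuclei)
  utils::write.csv(rep$comparison, file.path(out_dir, "group_comparison.csv"),
                   row.names = FALSE)
  if (!is.null(rep$correlations)) {
    utils::write.csv(rep$correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
  }

  med <- aggregate_patient(feats, min_nuclei)
  d <- merge(med, patients, by = "patient_id")
  covars <- c(setdiff(names(med), "patient_id"),
              intersect(c("leukocyte_count", "morphology_variant", grouping),
                        names(patients)))
  covars <- unique(covars)
  cox_rows <- list()
  for (cv in covars) {
    for (strat in c(FALSE, TRUE)) {
      if (strat && cv == strata) next # stratifying a variable on itself
      fit <- tryCatch({
        if (strat) cox_stratified(d, cv, strata) else cox_univariate(d, cv)
      }, error = function(e) e)
      cox_rows[[length(cox_rows) + 1L]] <- if (inherits(fit, "error")) {
        data.frame(covariate = cv, B = NA_real_, p = NA_real_,
                   stratified = strat, converged = FALSE,
                   note = conditionMessage(fit), stringsAsFactors = FALSE)
      } else {
        data.frame(covariate = cv, B = fit$coefficient, p = fit$p_value,
                   stratified = strat, converged = fit$converged,
                   note = "", stringsAsFactors = FALSE)
      }
    }
  }
  cox_df <- do.call(rbind, cox_rows)
  utils::write.csv(cox_df, file.path(out_dir, "cox.csv"), row.names = FALSE)

  meta <- list(
    features_csv = features_csv, patients_csv = patients_csv,
    grouping = grouping, strata = strata, min_nuclei = min_nuclei,
    ci_level = ci_level, seed = seed,
    package = "chromatex",
    version = as.character(utils::packageVersion("chromatex")))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(comparison = rep$comparison,
                 correlations = rep$correlations, cox = cox_df))
}

#' Simulate a cohort and write it to disk
#'
#' @param config a [generator_config()] or path to a JSON config
#' @param out_dir output directory
#' @return `out_dir`, invisibly
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_generator_config(config)
  write_cohort(generate_cohort(config), out_dir)
}

#' Read a generator configuration from JSON
#'
#' @param path JSON file as written by [write_cohort()]
#' @return a `generator_config`
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gp <- lapply(raw$group_params, as.list)
  sp <- lapply(raw$survival_params, as.list)
  generator_config(
    seed = raw$seed,
    n_patients_per_group = raw$n_patients_per_group,
    nuclei_per_patient = raw$nuclei_per_patient,
    group_params = gp, survival_params = sp,
    calibration_um_per_px = raw$calibration_um_per_px)
}
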