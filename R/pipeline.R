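#' Cohort descriptive summary
#'
#' Median with 25th/75th percentiles (linear interpolation) of the per-scan
#' volumes and per-pair change determinants — the descriptive layout of a
#' longitudinal volumetry cohort table.
#'
#' @param scans per-scan cohort table.
#' @param records per-pair change records (from \code{\link{change_records}}).
#' @return data.frame: variable, n, median, q25, q75.
#' @export
summarize_cohort <- function(scans, records) {
  one <- function(name, x) {
    x <- x[is.finite(x)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(variable = name, n = length(x),
               median = q[2], q25 = q[1], q75 = q[3])
  }
  out <- rbind(one("cv_ml", scans$cv_ml),
               one("dcv_ml", records$dcv_ml),
               one("scv_ml", records$scv_ml),
               one("fv_ml", scans$fv_ml),
               one("dfv_ml", records$dfv_ml),
               one("sfv_ml", records$sfv_ml))
  rownames(out) <- NULL
  out
}

#' Run the full volumetric progression analysis
#'
#' Orchestrates the table-mode pipeline end to end on a cohort: change
#' records (LSC-corrected deltas + regional subtractions), consensus
#' labeling (MC hierarchy, dichotomization), inter-rater agreement, the
#' four-predictor mixed model, and the delta-vs-subtraction model
#' comparison with cross-validated ROC, DeLong and exact binomial tests.
#' All randomness (fold assignment) derives from \code{seed}; rerunning
#' with an identical cohort and seed reproduces every number.
#'
#' @param cohort a \code{\link{phantom_cohort}}, or a list with elements
#'   \code{scans}, \code{ratings}, \code{mc_sources} read from CSV.
#' @param lsc \code{\link{lsc_params}}.
#' @param progression_categories see \code{\link{dichotomize}}.
#' @param n_folds,grouping cross-validation settings.
#' @param seed fold-assignment seed.
#' @param out_dir if non-NULL, write the report bundle (summary, labeled
#'   records, coefficients, ROC points, run metadata) as CSV/JSON-less
#'   plain text under this directory.
#' @return list of class \code{gliovol_report}: \code{summary} (descriptive
#'   table), \code{records} (labeled change records), \code{kappa_raters},
#'   \code{kappa_rc_mc}, \code{comparison} (\code{model_comparison}),
#'   \code{seed}.
#' @export
run_pipeline <- function(cohort, lsc = lsc_params(),
                         progression_categories = 5L,
                         n_folds = 5L, grouping = "patient",
                         seed = 1L, out_dir = NULL) {
  for (el in c("scans", "ratings", "mc_sources"))
    if (is.null(cohort[[el]])) stop("cohort is missing element: ", el)
  records <- change_records(cohort$scans, lsc)
  records <- label_records(records, cohort$mc_sources,
                           progression_categories)
  ra <- cohort$ratings[cohort$ratings$rater == "a", ]
  rb <- cohort$ratings[cohort$ratings$rater == "b", ]
  ra <- ra[order(ra$patient_id, ra$scan_index), ]
  rb <- rb[order(rb$patient_id, rb$scan_index), ]
  kappa_raters <- cohens_kappa(ra$category, rb$category)
  mcres <- resolve_mc(cohort$mc_sources$histo, cohort$mc_sources$board,
                      cohort$mc_sources$rc)
  kappa_rc_mc <- cohens_kappa(cohort$mc_sources$rc, mcres$mc)
  comparison <- compare_models(records, n_folds = n_folds,
                               fold_seed = seed, grouping = grouping)
  report <- structure(
    list(summary = summarize_cohort(cohort$scans, records),
         records = records,
         kappa_raters = kappa_raters,
         kappa_rc_mc = kappa_rc_mc,
         comparison = comparison,
         n_excluded = sum(is.na(records$progression)),
         seed = as.integer(seed)),
    class = "gliovol_report")
  if (!is.null(out_dir)) .write_report(report, cohort, out_dir)
  report
}

#' @export
print.gliovol_report <- function(x, ...) {
  cat("== Longitudinal volumetry report (seed ", x$seed, ") ==\n", sep = "")
  print(x$summary, digits = 4)
  cat(sprintf("Inter-rater kappa %.3f; RC vs MC kappa %.3f; %d pairs excluded (ratings 0/1)\n",
              x$kappa_raters, x$kappa_rc_mc, x$n_excluded))
  print(x$comparison)
  invisible(x)
}

.config_hash <- function(report) {
  # cheap content fingerprint: no digest dependency needed
  v <- c(report$seed, nrow(report$records), report$kappa_raters,
         report$comparison$delta$auc, report$comparison$subtraction$auc)
  sprintf("%08x", sum(round(v * 1e6)) %% .Machine$integer.max)
}

.write_report <- function(report, cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# gliovol report | seed=%d | config=%s",
                 report$seed, .config_hash(report))
  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  wcsv(report$summary, "summary.csv")
  wcsv(report$records, "change_records.csv")
  wcsv(report$comparison$joint$coefficients, "glmm_coefficients.csv")
  roc_d <- report$comparison$delta$roc$points
  roc_s <- report$comparison$subtraction$roc$points
  roc_d$model <- "delta"; roc_s$model <- "subtraction"
  wcsv(rbind(roc_d, roc_s), "roc_points.csv")
  cmp <- report$comparison
  probs <- rbind(
    data.frame(model = "delta", progression = cmp$delta$cv$progression,
               prob = cmp$delta$cv$prob),
    data.frame(model = "subtraction",
               progression = cmp$subtraction$cv$progression,
               prob = cmp$subtraction$cv$prob))
  wcsv(probs, "predicted_probabilities.csv")
  wcsv(data.frame(
    metric = c("auc_delta", "auc_subtraction",
               "auc_fold_mean_delta", "auc_fold_mean_subtraction",
               "accuracy_delta", "accuracy_subtraction",
               "binomial_p_delta", "binomial_p_subtraction",
               "delong_z", "delong_p", "nir",
               "kappa_raters", "kappa_rc_mc"),
    value = c(cmp$delta$auc, cmp$subtraction$auc,
              cmp$delta$auc_fold_mean, cmp$subtraction$auc_fold_mean,
              cmp$delta$accuracy, cmp$subtraction$accuracy,
              cmp$delta$binomial_p, cmp$subtraction$binomial_p,
              cmp$delong$statistic, cmp$delong$p_value, cmp$nir,
              report$kappa_raters, report$kappa_rc_mc)),
    "metrics.csv")
  invisible(out_dir)
}

#' Segment one rendered phantom scan and measure both compartments
#'
#' Image-mode worker: runs the semi-automated segmentation on a rendered
#' scan's two channels, seeding from the ground-truth masks (standing in
#' for the rater's two-plane input), and returns measured vs true volumes.
#'
#' @param scan one element of a \code{\link{render_phantom_images}} result.
#' @param tolerance_k region-growing band half-width.
#' @return data.frame: compartment, true_ml, measured_ml, rel_error.
#' @export
segment_scan <- function(scan, tolerance_k = 2.5) {
  one <- function(image, truth_mask, compartment) {
    seeds <- seeds_from_mask(truth_mask)
    m <- segment_semiauto(image, seeds$axial, seeds$coronal,
                          tolerance_k = tolerance_k,
                          compartment = compartment)
    true_ml <- mask_volume_ml(truth_mask)
    meas <- mask_volume_ml(m)
    data.frame(compartment = compartment, true_ml = true_ml,
               measured_ml = meas,
               rel_error = (meas - true_ml) / true_ml)
  }
  rbind(one(scan$mprage, scan$cv_mask, "CV"),
        one(scan$flair, scan$fv_mask, "FV"))
}
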