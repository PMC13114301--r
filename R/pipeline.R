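#' Run the full toxicity-modelling pipeline on a cohort
#'
#' Orchestrates featurization (per-zone PCA + indicators), min-max scaling
#' and collinearity pruning, toxicity labelling from the IPSS series, the
#' univariate screen, sequential backward selection with shuffle-split
#' validation, and importance-by-removal reporting.  Optionally writes the
#' standard output bundle (`features.csv`, `uva.csv`, `model_report.json`,
#' `roc.csv`, `importance.csv`) to a directory.
#'
#' @param cohort a `synthetic_cohort` (or any list with `dvhs`,
#'   `indicators`, `records`).
#' @param n_repeats shuffle-split repeats for the SBS inner loop.
#' @param final_repeats repeats for the final performance evaluation
#'   (default: same as `n_repeats`).
#' @param test_fraction held-out fraction per split.
#' @param seed master seed for splits (and PSO when `tune = TRUE`).
#' @param stop_level retained-feature target (default `floor(n/10)`).
#' @param tune run the particle-swarm hyperparameter search before SBS.
#' @param r_threshold Pearson pruning cutoff.
#' @param out_dir optional output directory.
#' @return list of class `pipeline_result`: `features` (pruned
#'   `feature_table`), `labels`, `uva`, `fit` (`sbs_svm`), `importance`.
#' @export
run_pipeline <- function(cohort, n_repeats = 200,
                         final_repeats = n_repeats,
                         test_fraction = 0.2, seed = 1,
                         stop_level = NULL, tune = FALSE,
                         r_threshold = 0.9, out_dir = NULL) {
  ft <- build_feature_table(cohort$dvhs, cohort$indicators)
  ftp <- scale_and_prune(ft, r_threshold = r_threshold)
  labels <- vapply(cohort$records, function(r)
    label_toxicity(r$baseline, r$times, r$scores), integer(1))
  uva <- uva_screen(ftp$values, labels)
  scheme <- split_scheme(n_repeats, test_fraction, seed = seed)
  fscheme <- split_scheme(final_repeats, test_fraction, seed = seed)
  fit <- sbs_select(ftp$values, labels, scheme = scheme,
                    stop_level = stop_level, tune = tune,
                    final_scheme = fscheme)
  imp <- importance_by_removal(fit, ftp$values, labels)
  res <- structure(list(features = ftp, labels = labels, uva = uva,
                        fit = fit, importance = imp,
                        params = list(n_repeats = n_repeats,
                                      final_repeats = final_repeats,
                                      test_fraction = test_fraction,
                                      seed = seed,
                                      r_threshold = r_threshold)),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d patients, %d features after pruning (%d pruned)\n",
              nrow(x$features$values), ncol(x$features$values),
              length(x$features$pruned)))
  cat(sprintf("  toxicity prevalence %.2f; %d UVA-significant features\n",
              mean(x$labels), sum(x$uva$significant, na.rm = TRUE)))
  print(x$fit)
  invisible(x)
}

#' Write the pipeline output bundle
#'
#' @param res a `pipeline_result`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feat <- data.frame(patient_id = rownames(res$features$values),
                     res$features$values, check.names = FALSE)
  utils::write.csv(feat, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(res$uva, file.path(out_dir, "uva.csv"), row.names = FALSE)
  utils::write.csv(res$fit$roc, file.path(out_dir, "roc.csv"),
                   row.names = FALSE)
  utils::write.csv(res$importance, file.path(out_dir, "importance.csv"),
                   row.names = FALSE)
  report <- list(
    n_patients = nrow(res$features$values),
    n_features_post_pruning = ncol(res$features$values),
    pruned_features = res$features$pruned,
    selected_features = res$fit$selected,
    mean_auc = res$fit$mean_auc,
    accuracy = res$fit$accuracy,
    sensitivity = res$fit$sensitivity,
    specificity = res$fit$specificity,
    hyperparameters = as.list(res$fit$hyper),
    params = res$params,
    trace = res$fit$trace)
  jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
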