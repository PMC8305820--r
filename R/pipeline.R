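#' Configuration for an end-to-end radiomics run
#'
#' Bundles the cohort specification (or a manifest CSV of an existing
#' image cohort), the extraction, selection and classification settings,
#' and a single master seed from which every random stage derives a named
#' sub-stream.
#'
#' @param cohort a [cohort_spec()] to synthesize a cohort, or the path of
#'   a manifest CSV written by [write_cohort()].
#' @param ng,wavelet,n_bins extraction settings (see
#'   [extract_features()]).
#' @param folds,rule,criterion selection settings (see
#'   [cv_lasso_logistic()] and [select_features()]).
#' @param cv_grouping `"slice"` (default, mirrors slice-level selection)
#'   or `"patient"` (leakage-safe grouped folds).
#' @param classifiers character vector of classifier kinds to train.
#' @param compare_all_features also evaluate with all 180 features
#'   (selection bypassed) for the selected-vs-all comparison.
#' @param seed master seed.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), ng = 32,
                            wavelet = "haar", n_bins = 32, folds = 5,
                            rule = "lambda_min",
                            criterion = "deviance",
                            cv_grouping = c("slice", "patient"),
                            classifiers = classifier_kinds,
                            compare_all_features = FALSE,
                            seed = 1, out_dir = NULL) {
  cv_grouping <- match.arg(cv_grouping)
  stopifnot(all(classifiers %in% classifier_kinds))
  structure(list(cohort = cohort, ng = ng, wavelet = wavelet,
                 n_bins = n_bins, folds = folds, rule = rule,
                 criterion = criterion, cv_grouping = cv_grouping,
                 classifiers = classifiers,
                 compare_all_features = compare_all_features,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    if (grepl("^\\[", msg)) stop(e)  # already stage-tagged
    stop_stage(stage, "%s", msg)
  })
}

#' Run the full radiomics pipeline
#'
#' Generate-or-load cohort, extract the 180-feature table, fit the
#' training min-max normalizer, select features by cross-validated
#' LASSO-logistic deviance, train the requested classifiers on the
#' selected features, and evaluate them on the validation patients at
#' slice and patient granularity. Re-running with the same configuration
#' reproduces every artifact (all randomness derives from the master
#' seed).
#'
#' @param config a [pipeline_config()].
#' @return object of class `radiomics_pipeline_run`: `manifest`,
#'   `feature_table` (raw), `normalizer`, `cv` (the
#'   `cv_lasso_logistic`), `selection` (selected features +
#'   coefficients), `models`, `report` (a `radiomics_eval`),
#'   `report_all_features` (when requested) and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  cohort <- run_stage("synthetic_cohort", {
    if (inherits(config$cohort, "cohort_spec")) generate_cohort(config$cohort)
    else load_cohort(config$cohort)
  })
  manifest <- cohort$manifest

  ft <- run_stage("texture_features",
    extract_feature_table(cohort, ng = config$ng, wavelet = config$wavelet,
                          n_bins = config$n_bins))

  norm <- run_stage("feature_selection", fit_normalizer(ft))
  ftn <- apply_normalizer(norm, ft)
  tr <- ftn$split == "training"
  if (!any(!tr)) stop_stage("classification_eval", "empty validation split")
  fn <- radiomics_feature_names()
  xtr <- as.matrix(ftn[tr, fn])
  ytr <- ftn$class_label[tr]
  xval <- as.matrix(ftn[!tr, fn])

  cv <- run_stage("feature_selection",
    cv_lasso_logistic(xtr, ytr, k = config$folds,
                      seed = sub_seed(seed, "cv"),
                      groups = if (config$cv_grouping == "patient")
                        ftn$patient_id[tr] else NULL,
                      criterion = config$criterion))
  selection <- select_features(cv, rule = config$rule)
  selection_fallback <- FALSE
  if (nrow(selection) == 0) {
    # CV preferred the null model (no class signal). The classifiers
    # still need inputs, so fall back to the largest lambda at which any
    # feature enters the path; with no real signal this yields
    # chance-level classifiers rather than a dead pipeline.
    entering <- which(cv$nzero > 0)
    if (length(entering) == 0)
      stop_stage("feature_selection",
                 "no feature enters the path on any lambda")
    selection <- select_features_at(cv, cv$lambda[entering[1]])
    selection_fallback <- TRUE
    message("selection rule '", config$rule, "' selected no features; ",
            "falling back to the first feature(s) entering the path")
  }

  fit_and_eval <- function(feature_set) {
    models <- lapply(config$classifiers, function(kind)
      run_stage("classification_eval",
        train_classifier(xtr[, feature_set, drop = FALSE], ytr, kind,
                         seed = sub_seed(seed, paste0("clf_", kind)))))
    names(models) <- config$classifiers
    run_stage("classification_eval",
      evaluate_classifiers(models, xval[, feature_set, drop = FALSE],
                           ftn$class_label[!tr], ftn$patient_id[!tr],
                           manifest))
  }
  models_features <- selection$feature
  report <- fit_and_eval(models_features)
  report_all <- if (isTRUE(config$compare_all_features)) fit_and_eval(fn)

  out <- structure(list(
    manifest = manifest, feature_table = ft, normalizer = norm, cv = cv,
    selection = selection, report = report,
    report_all_features = report_all,
    provenance = list(
      master_seed = seed,
      selection_fallback = selection_fallback,
      sub_seeds = c(cv = sub_seed(seed, "cv"),
                    stats::setNames(vapply(config$classifiers, function(k)
                      sub_seed(seed, paste0("clf_", k)), integer(1)),
                      paste0("clf_", config$classifiers))),
      config = unclass(config[setdiff(names(config), "cohort")]),
      cohort_seed = if (inherits(config$cohort, "cohort_spec"))
        config$cohort$seed else NA_integer_,
      package_version = as.character(utils::packageVersion("sonoradiomics")))),
    class = "radiomics_pipeline_run")

  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config)
  out
}

write_pipeline_artifacts <- function(run, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(run$manifest),
            file.path(config$out_dir, "manifest.csv"), row.names = FALSE)
  write_feature_table(run$feature_table,
                      file.path(config$out_dir, "features.csv"))
  jsonlite::write_json(
    list(lambda = run$cv$lambda, cv_deviance_mean = run$cv$cvm,
         cv_deviance_se = run$cv$cvse, lambda_min = run$cv$lambda_min,
         lambda_1se = run$cv$lambda_1se, rule = config$rule,
         selected = run$selection),
    file.path(config$out_dir, "selection.json"),
    auto_unbox = TRUE, digits = NA)
  write.csv(eval_metrics(run$report),
            file.path(config$out_dir, "metrics.csv"), row.names = FALSE)
  roc <- do.call(rbind, lapply(names(run$report$results), function(m)
    do.call(rbind, lapply(c("slice", "patient"), function(g)
      cbind(classifier = m, granularity = g,
            run$report$results[[m]][[g]]$roc_points)))))
  write.csv(roc, file.path(config$out_dir, "roc_points.csv"),
            row.names = FALSE)
  jsonlite::write_json(run$provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' @export
print.radiomics_pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Radiomics pipeline run (master seed %d)\n",
              x$provenance$master_seed))
  cat(sprintf("  cohort: %d patients / %d slices (%d validation slices)\n",
              length(unique(m$patient_id)), nrow(m),
              sum(m$split == "validation")))
  cat(sprintf("  selected %d of 180 features at lambda = %.5g\n",
              nrow(x$selection), x$cv$lambda_min))
  print(x$report)
  if (!is.null(x$report_all_features)) {
    cat("all-180-feature comparison:\n")
    print(x$report_all_features)
  }
  invisible(x)
}

#' @export
summary.radiomics_pipeline_run <- function(object, ...) {
  list(metrics = eval_metrics(object$report),
       selection = object$selection,
       lambda_min = object$cv$lambda_min,
       metrics_all_features = if (!is.null(object$report_all_features))
         eval_metrics(object$report_all_features))
}
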