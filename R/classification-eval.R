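classifier_kinds <- c("logistic_regression", "svm", "random_forest", "knn")

default_classifier_params <- function(kind) {
  switch(kind,
    logistic_regression = list(l2 = 1e-3),
    svm = list(kernel = "radial", cost = 1),
    random_forest = list(ntree = 500),
    knn = list(k = 5),
    stop_stage("classification_eval", "unknown classifier kind '%s'", kind))
}

#' Train one of the four slice classifiers
#'
#' Trains a probabilistic binary classifier of slice feature vectors with
#' `"MN"` as the positive class: ridge-regularized logistic regression
#' (light L2, via glmnet), an RBF-kernel SVM with probability outputs
#' (e1071), a 500-tree random forest (randomForest), or unweighted
#' k-nearest neighbours (class, k = 5). All stochastic trainers are
#' seeded, so the same seed reproduces identical models and predictions.
#'
#' @param x numeric matrix of (selected, normalized) features.
#' @param y class labels: factor/character with values `"MN"`/`"IgA"`, or
#'   0/1 with 1 = MN.
#' @param kind one of `"logistic_regression"`, `"svm"`,
#'   `"random_forest"`, `"knn"`.
#' @param seed integer seed (default 1).
#' @param params named list overriding the kind's default
#'   hyperparameters (`l2`; `kernel`, `cost`; `ntree`; `k`).
#' @return object of class `radiomics_classifier`; its `predict` method
#'   returns the probability of MN per row.
#' @export
train_classifier <- function(x, y, kind = classifier_kinds, seed = 1,
                             params = list()) {
  if (length(kind) > 1) kind <- kind[1]
  if (!kind %in% classifier_kinds)
    stop_stage("classification_eval", "unknown classifier kind '%s'", kind)
  x <- as.matrix(x)
  yb <- binarize_response(y)
  if (min(table(yb)) < 2)
    stop_stage("classification_eval", "need >= 2 training rows per class")
  yf <- factor(ifelse(yb == 1, "MN", "IgA"), levels = c("IgA", "MN"))
  p <- utils::modifyList(default_classifier_params(kind), params)
  set.seed(seed)
  # glmnet needs >= 2 columns; a zero column is inert under the ridge fit
  pad <- kind == "logistic_regression" && ncol(x) < 2
  model <- switch(kind,
    logistic_regression = glmnet::glmnet(
      if (pad) cbind(x, `.pad` = 0) else x, yf, family = "binomial",
      alpha = 0, lambda = p$l2),
    svm = e1071::svm(x, yf, kernel = p$kernel, cost = p$cost,
                     probability = TRUE),
    random_forest = randomForest::randomForest(x, yf, ntree = p$ntree),
    knn = list(train = x, cl = yf, k = p$k))
  structure(list(kind = kind, model = model, params = p, seed = seed,
                 features = colnames(x), pad = pad),
            class = "radiomics_classifier")
}

#' @export
print.radiomics_classifier <- function(x, ...) {
  cat(sprintf("radiomics classifier: %s (%d features, seed %d)\n",
              x$kind, length(x$features), x$seed))
  invisible(x)
}

#' Predict MN probabilities for new slices
#'
#' @param object a `radiomics_classifier`.
#' @param newx feature matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of P(MN) per row.
#' @export
predict.radiomics_classifier <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (!is.null(object$features) && !is.null(colnames(newx)))
    newx <- newx[, object$features, drop = FALSE]
  switch(object$kind,
    logistic_regression =
      as.numeric(predict(object$model,
                         if (isTRUE(object$pad)) cbind(newx, `.pad` = 0)
                         else newx, type = "response")),
    svm = {
      pr <- attr(predict(object$model, newx, probability = TRUE),
                 "probabilities")
      as.numeric(pr[, "MN"])
    },
    random_forest =
      as.numeric(predict(object$model, newx, type = "prob")[, "MN"]),
    knn = {
      set.seed(object$seed)  # knn breaks vote ties at random
      pred <- class::knn(object$model$train, newx, object$model$cl,
                         k = object$model$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "MN", win, 1 - win)
    })
}

#' Aggregate slice probabilities to patient probabilities
#'
#' The mean predicted probability over all slices of a patient serves as
#' that patient's probability; slice order is immaterial.
#'
#' @param probs numeric vector of per-slice probabilities.
#' @param patient_ids patient id per slice.
#' @param manifest optional manifest; slices whose patient is absent from
#'   it raise an orphan-slice error.
#' @return named numeric vector, one probability per patient.
#' @export
aggregate_to_patients <- function(probs, patient_ids, manifest = NULL) {
  stopifnot(length(probs) == length(patient_ids))
  if (!is.null(manifest)) {
    orphan <- setdiff(patient_ids, manifest$patient_id)
    if (length(orphan) > 0)
      stop_stage("classification_eval", "orphan slice(s): patient(s) %s not in manifest",
                 paste(orphan, collapse = ", "))
  }
  out <- tapply(probs, patient_ids, mean)
  out[unique(patient_ids)]  # keep first-appearance order
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Thresholds at every unique score give the empirical ROC; the AUC is
#' the trapezoidal area, which (with tied scores contributing half) is
#' exactly the Mann-Whitney U statistic divided by \eqn{n_1 n_0}: the
#' probability a random positive outscores a random negative, ties
#' counting one half. All scores equal gives AUC 0.5.
#'
#' @param labels 0/1 (or `"MN"`/`"IgA"`) true labels; both classes must
#'   be present.
#' @param scores numeric classifier scores, larger = more MN-like.
#' @return list with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(labels, scores) {
  y <- binarize_response(labels)
  stopifnot(length(y) == length(scores))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop_stage("classification_eval", "ROC needs both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & y == 0), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fp / n0),
                    tpr = c(0, tp / n1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

binary_metrics <- function(labels, probs, threshold = 0.5) {
  y <- binarize_response(labels)
  pred <- as.integer(probs >= threshold)  # ties -> positive (MN)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  roc <- roc_auc(y, probs)
  list(accuracy = (tp + tn) / length(y), auc = roc$auc,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
       roc_points = roc$points)
}

#' Evaluate trained classifiers at slice and patient granularity
#'
#' For each classifier, slice probabilities on the validation rows give
#' the slice-level metrics; the per-patient mean probabilities (see
#' [aggregate_to_patients()]) give the patient-level metrics. Sensitivity
#' is the true-positive rate for MN, specificity the true-negative rate
#' for IgA; predicted labels threshold the probabilities at 0.5 (ties
#' count as MN), and accuracy uses those same labels as the confusion
#' matrix.
#'
#' @param models named list of `radiomics_classifier` objects.
#' @param x validation feature matrix.
#' @param labels validation slice labels (`"MN"`/`"IgA"` or 0/1).
#' @param patient_ids validation patient id per slice.
#' @param manifest optional manifest for orphan-slice checking.
#' @return object of class `radiomics_eval`: per classifier and
#'   granularity (`slice`, `patient`) the accuracy, AUC, sensitivity,
#'   specificity, confusion counts and ROC points.
#' @export
evaluate_classifiers <- function(models, x, labels, patient_ids,
                                 manifest = NULL) {
  if (nrow(as.matrix(x)) == 0)
    stop_stage("classification_eval", "empty validation split")
  if (inherits(models, "radiomics_classifier")) models <- list(models)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, character(1), "kind")
  y <- binarize_response(labels)
  pat_label <- tapply(y, patient_ids, function(v) v[1])[unique(patient_ids)]
  res <- lapply(models, function(m) {
    ps <- predict(m, x)
    pp <- aggregate_to_patients(ps, patient_ids, manifest)
    list(slice = binary_metrics(y, ps),
         patient = binary_metrics(as.numeric(pat_label), as.numeric(pp)),
         slice_probs = ps, patient_probs = pp)
  })
  structure(list(results = res, n_slices = length(y),
                 n_patients = length(pat_label)), class = "radiomics_eval")
}

#' Metrics of an evaluation as a data frame
#'
#' @param report a `radiomics_eval`.
#' @return data frame with one row per classifier x granularity.
#' @export
eval_metrics <- function(report) {
  stopifnot(inherits(report, "radiomics_eval"))
  rows <- list()
  for (m in names(report$results)) {
    for (g in c("slice", "patient")) {
      met <- report$results[[m]][[g]]
      rows[[paste(m, g)]] <- data.frame(
        classifier = m, granularity = g, accuracy = met$accuracy,
        auc = met$auc, sensitivity = met$sensitivity,
        specificity = met$specificity,
        tp = met$confusion["tp"], fn = met$confusion["fn"],
        tn = met$confusion["tn"], fp = met$confusion["fp"],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.radiomics_eval <- function(x, ...) {
  cat(sprintf("Radiomics evaluation: %d classifiers, %d slices / %d patients\n",
              length(x$results), x$n_slices, x$n_patients))
  m <- eval_metrics(x)
  m[, c("accuracy", "auc", "sensitivity", "specificity")] <-
    round(m[, c("accuracy", "auc", "sensitivity", "specificity")], 4)
  print(m[, 1:6])
  invisible(x)
}

#' @export
summary.radiomics_eval <- function(object, ...) eval_metrics(object)

#' @export
plot.radiomics_eval <- function(x, granularity = "patient", ...) {
  cols <- seq_along(x$results)
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "false-positive rate", ylab = "true-positive rate",
                 main = sprintf("ROC (%s level)", granularity), ...)
  for (i in cols) {
    pts <- x$results[[i]][[granularity]]$roc_points
    graphics::lines(pts$fpr, pts$tpr, col = i)
  }
  graphics::legend("bottomright", names(x$results), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
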