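#' Fit a min-max normalizer on training rows
#'
#' Learns per-feature minimum and maximum from the training rows only
#' (rows with `split == "training"` when a feature table is given).
#' Applying the normalizer maps training columns into `[0, 1]`; rows
#' transformed later (e.g. validation) use the training parameters and may
#' fall outside `[0, 1]` — they are not clipped. Constant training
#' features are flagged and mapped to 0.
#'
#' @param table a feature table (data frame with the 180 canonical
#'   columns) or a plain numeric matrix.
#' @return object of class `minmax_normalizer` with `min`, `max`,
#'   `constant` (logical flags) per feature.
#' @export
fit_normalizer <- function(table) {
  x <- normalizer_matrix(table, training_only = TRUE)
  if (nrow(x) < 2)
    stop_stage("feature_selection", "need >= 2 training rows to fit normalizer")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  structure(list(min = mins, max = maxs, constant = maxs <= mins,
                 features = colnames(x)), class = "minmax_normalizer")
}

normalizer_matrix <- function(table, training_only = FALSE) {
  if (is.matrix(table)) return(table)
  fn <- intersect(radiomics_feature_names(), names(table))
  if (length(fn) == 0) {  # not a canonical table: take all numeric columns
    fn <- names(table)[vapply(table, is.numeric, logical(1))]
    fn <- setdiff(fn, "slice_index")
  }
  rows <- if (training_only && "split" %in% names(table))
    table$split == "training" else rep(TRUE, nrow(table))
  as.matrix(table[rows, fn, drop = FALSE])
}

#' Apply a fitted min-max normalizer
#'
#' @param params a `minmax_normalizer`.
#' @param table feature table or matrix with exactly the fitted columns.
#' @return the input with feature columns rescaled by the training
#'   min/max.
#' @export
apply_normalizer <- function(params, table) {
  stopifnot(inherits(params, "minmax_normalizer"))
  x <- normalizer_matrix(table)
  if (!identical(colnames(x), params$features))
    stop_stage("feature_selection",
               "column mismatch: normalizer fitted on different features")
  rng <- params$max - params$min
  rng[params$constant] <- 1  # constant features map to 0
  scaled <- sweep(sweep(x, 2, params$min), 2, rng, "/")
  scaled[, params$constant] <- 0
  if (is.matrix(table)) return(scaled)
  table[, colnames(x)] <- scaled
  table
}

#' @export
print.minmax_normalizer <- function(x, ...) {
  cat(sprintf("min-max normalizer: %d features (%d constant in training)\n",
              length(x$features), sum(x$constant)))
  invisible(x)
}

lambda_grid <- function(x, y, nlambda, lambda_min_ratio) {
  lmax <- max(abs(crossprod(x, y - mean(y)))) / length(y)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' L1-penalized logistic regression path
#'
#' Fits the lasso-logistic coefficient path
#' \deqn{\min_{b_0,\beta} \frac1n\sum_i \log(1+e^{\eta_i}) - y_i\eta_i
#'       + \lambda \|\beta\|_1,\qquad \eta_i = b_0 + x_i^\top\beta,}
#' with the intercept unpenalized, by cyclic coordinate descent with
#' soft-thresholding under the logistic 1/4 curvature bound (so the
#' objective is non-increasing at every update), warm-started along a
#' descending \eqn{\lambda} grid. The default grid has 100 log-spaced
#' values from \eqn{\lambda_{max} = \max_j |x_j^\top(y-\bar y)|/n} (where
#' every penalized coefficient is exactly zero) down to
#' \eqn{10^{-3}\lambda_{max}}. Features are assumed pre-normalized (the
#' pipeline applies 0-1 min-max scaling first); no internal
#' re-standardization is performed.
#'
#' @param x numeric matrix, n rows (slices) x p features.
#' @param y binary response: 0/1 vector or a factor/character vector in
#'   which `"MN"` (or the second level) codes 1.
#' @param lambda optional user grid (descending); default computed.
#' @param nlambda,lambda_min_ratio grid size and ratio of smallest to
#'   largest \eqn{\lambda}.
#' @param tol convergence threshold on the largest coefficient change in a
#'   full sweep (default 1e-7).
#' @param maxit maximum sweeps per \eqn{\lambda} (default 1e5).
#' @return object of class `lasso_logistic`: `lambda`, `a0` (intercepts),
#'   `beta` (p x nlambda sparse-in-content matrix), `df` (nonzero counts),
#'   `sweeps`, `nobs`, `feature_names`.
#' @export
lasso_logistic <- function(x, y, lambda = NULL, nlambda = 100,
                           lambda_min_ratio = 1e-3, tol = 1e-7,
                           maxit = 1e5) {
  x <- as.matrix(x)
  y <- binarize_response(y)
  if (length(unique(y)) < 2)
    stop_stage("feature_selection", "response has a single class")
  if (is.null(lambda))
    lambda <- lambda_grid(x, y, nlambda, lambda_min_ratio)
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  fit <- lasso_logistic_path_cpp(x, y, lambda, tol, as.integer(maxit))
  beta <- fit$beta
  rownames(beta) <- colnames(x)
  structure(list(lambda = lambda, a0 = fit$a0, beta = beta,
                 df = colSums(beta != 0), sweeps = fit$sweeps,
                 nobs = nrow(x),
                 feature_names = colnames(x)),
            class = "lasso_logistic")
}

binarize_response <- function(y) {
  if (is.factor(y)) return(as.numeric(y == levels(y)[2]))
  if (is.character(y)) return(as.numeric(y == "MN"))
  stopifnot(all(y %in% c(0, 1)))
  as.numeric(y)
}

#' @export
print.lasso_logistic <- function(x, ...) {
  cat(sprintf("L1 logistic path: %d features, %d lambda values (%.3g .. %.3g)\n",
              nrow(x$beta), length(x$lambda), max(x$lambda), min(x$lambda)))
  cat(sprintf("  nonzero coefficients: %d at lambda_max, %d at the smallest lambda\n",
              x$df[1], x$df[length(x$df)]))
  invisible(x)
}

nearest_lambda <- function(object, s) which.min(abs(log(object$lambda) - log(s)))

#' @export
coef.lasso_logistic <- function(object, s = min(object$lambda), ...) {
  l <- nearest_lambda(object, s)
  c(`(Intercept)` = object$a0[l], object$beta[, l])
}

#' @export
predict.lasso_logistic <- function(object, newx, s = min(object$lambda),
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  l <- nearest_lambda(object, s)
  eta <- drop(object$a0[l] + as.matrix(newx) %*% object$beta[, l])
  if (type == "link") eta else plogis(eta)
}

#' @export
plot.lasso_logistic <- function(x, ...) {
  graphics::matplot(log(x$lambda), t(x$beta), type = "l", lty = 1,
                    xlab = expression(log(lambda)), ylab = "coefficient",
                    main = "L1 logistic coefficient path", ...)
  invisible(x)
}

#' Mean binomial deviance
#'
#' \eqn{(-2/n)\sum_i y_i\ln p_i + (1-y_i)\ln(1-p_i)}, probabilities
#' clamped to `[1e-12, 1 - 1e-12]`. A constant prediction of 0.5 gives
#' \eqn{2\ln 2 \approx 1.3863}.
#'
#' @param y 0/1 response.
#' @param p predicted probabilities.
#' @return scalar deviance.
#' @export
binomial_deviance <- function(y, p) {
  p <- clamp(p, 1e-12, 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

make_stratified_folds <- function(y, k, seed, groups = NULL) {
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    fold <- integer(length(y))
    if (is.null(groups)) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      # fold unit = group (patient): stratify groups by their class
      gtab <- unique(data.frame(g = groups, y = y, stringsAsFactors = FALSE))
      gfold <- integer(nrow(gtab))
      for (cls in unique(gtab$y)) {
        idx <- which(gtab$y == cls)
        gfold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      fold <- gfold[match(groups, gtab$g)]
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold == f])) == 2, logical(1)))
    if (ok) return(fold)
  }
  stop_stage("feature_selection",
             "could not draw folds with both classes after 10 attempts")
}

#' Cross-validated LASSO-logistic feature selection
#'
#' Fits the full [lasso_logistic()] path, then k-fold cross-validates the
#' held-out binomial deviance (and held-out AUC) along the same
#' \eqn{\lambda} grid. Folds are stratified by class; by default the fold
#' unit is the slice (each row independent), or pass `groups` (patient
#' ids) for patient-grouped folds, the leakage-safe alternative when
#' several rows share a patient. `lambda_min` minimizes the mean held-out
#' deviance (the default selection rule); `lambda_1se` is the largest
#' \eqn{\lambda} whose mean deviance is within one standard error of that
#' minimum. With `criterion = "auc"`, `lambda_min` instead maximizes the
#' mean held-out AUC.
#'
#' @inheritParams lasso_logistic
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param groups optional grouping vector (e.g. patient ids).
#' @param criterion `"deviance"` (default) or `"auc"`.
#' @return object of class `cv_lasso_logistic`: the full-data `fit`,
#'   `lambda`, `cvm` (mean held-out deviance), `cvse` (its standard
#'   error), `cv_auc`, `lambda_min`, `lambda_1se`, `nzero`, `fold`,
#'   `seed`, `criterion`.
#' @export
cv_lasso_logistic <- function(x, y, k = 5, seed = 1, lambda = NULL,
                              nlambda = 100, lambda_min_ratio = 1e-3,
                              groups = NULL,
                              criterion = c("deviance", "auc"),
                              tol = 1e-7, maxit = 1e5) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  yb <- binarize_response(y)
  if (k < 2) stop_stage("feature_selection", "k must be >= 2")
  fold <- make_stratified_folds(yb, k, seed, groups)
  if (is.null(lambda)) {
    # top of the grid covers every training fold's lambda_max, so the
    # path starts at the exact null model in every fold
    lmax <- max(vapply(0:k, function(f) {
      tr <- fold != f  # f = 0: full data
      max(abs(crossprod(x[tr, , drop = FALSE],
                        yb[tr] - mean(yb[tr])))) / sum(tr)
    }, numeric(1)))
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  fit <- lasso_logistic(x, yb, lambda = lambda, tol = tol, maxit = maxit)
  lam <- fit$lambda
  dev_fold <- matrix(NA_real_, k, length(lam))
  auc_fold <- matrix(NA_real_, k, length(lam))
  for (f in seq_len(k)) {
    tr <- fold != f
    pf <- lasso_logistic(x[tr, , drop = FALSE], yb[tr], lambda = lam,
                         tol = tol, maxit = maxit)
    eta <- sweep(x[!tr, , drop = FALSE] %*% pf$beta, 2, pf$a0, "+")
    prob <- plogis(eta)
    yv <- yb[!tr]
    dev_fold[f, ] <- apply(prob, 2, function(p) binomial_deviance(yv, p))
    auc_fold[f, ] <- apply(prob, 2, function(p)
      if (length(unique(yv)) == 2) roc_auc(yv, p)$auc else NA_real_)
  }
  cvm <- colMeans(dev_fold)
  cvse <- apply(dev_fold, 2, sd) / sqrt(k)
  cv_auc <- colMeans(auc_fold)
  i_min <- if (criterion == "deviance") which.min(cvm) else which.max(cv_auc)
  lambda_min <- lam[i_min]
  lambda_1se <- max(lam[cvm <= cvm[which.min(cvm)] + cvse[which.min(cvm)]])
  structure(list(fit = fit, lambda = lam, cvm = cvm, cvse = cvse,
                 cv_auc = cv_auc, lambda_min = lambda_min,
                 lambda_1se = lambda_1se, nzero = fit$df, fold = fold,
                 seed = seed, k = k, criterion = criterion),
            class = "cv_lasso_logistic")
}

#' @export
print.cv_lasso_logistic <- function(x, ...) {
  i <- which(x$lambda == x$lambda_min)
  cat(sprintf("%d-fold CV lasso-logistic (criterion: %s)\n", x$k, x$criterion))
  cat(sprintf("  lambda_min = %.5g (%d nonzero, CV deviance %.4f +/- %.4f)\n",
              x$lambda_min, x$nzero[i], x$cvm[i], x$cvse[i]))
  j <- which(x$lambda == x$lambda_1se)
  cat(sprintf("  lambda_1se = %.5g (%d nonzero)\n", x$lambda_1se, x$nzero[j]))
  invisible(x)
}

#' @export
plot.cv_lasso_logistic <- function(x, ...) {
  ll <- log(x$lambda)
  graphics::plot(ll, x$cvm, type = "l", xlab = expression(log(lambda)),
                 ylab = "CV binomial deviance",
                 ylim = range(x$cvm - x$cvse, x$cvm + x$cvse), ...)
  graphics::arrows(ll, x$cvm - x$cvse, ll, x$cvm + x$cvse, angle = 90,
                   code = 3, length = 0.02, col = "grey60")
  graphics::abline(v = log(c(x$lambda_min, x$lambda_1se)), lty = 2)
  graphics::axis(3, at = ll[seq(1, length(ll), length.out = 10)],
                 labels = x$nzero[seq(1, length(ll), length.out = 10)])
  invisible(x)
}

#' @export
coef.cv_lasso_logistic <- function(object, s = object$lambda_min, ...) {
  coef(object$fit, s = s)
}

#' @export
predict.cv_lasso_logistic <- function(object, newx,
                                      s = object$lambda_min, ...) {
  predict(object$fit, newx, s = s, ...)
}

#' Selected features at a chosen penalty
#'
#' Names and coefficients of the nonzero-coefficient features at the
#' rule's \eqn{\lambda}, sorted by decreasing coefficient magnitude (ties
#' broken by canonical name order).
#'
#' @param result a `cv_lasso_logistic`.
#' @param rule `"lambda_min"` (default, the smallest-CV-deviance rule),
#'   `"lambda_1se"`, or `"lambda_max"` (the null model, empty selection).
#' @return data frame with columns `feature`, `coefficient`.
#' @export
select_features <- function(result, rule = c("lambda_min", "lambda_1se",
                                             "lambda_max")) {
  stopifnot(inherits(result, "cv_lasso_logistic"))
  rule <- match.arg(rule)
  s <- switch(rule, lambda_min = result$lambda_min,
              lambda_1se = result$lambda_1se,
              lambda_max = max(result$lambda))
  select_features_at(result, s)
}

# nonzero coefficients at an arbitrary grid lambda, canonical ordering
select_features_at <- function(result, s) {
  b <- coef(result$fit, s = s)[-1]
  nz <- which(b != 0)
  out <- data.frame(feature = names(b)[nz], coefficient = unname(b[nz]),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$coefficient), out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
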