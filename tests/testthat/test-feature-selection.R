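make_xy <- function(n = 120, p = 8, seed = 5, beta = c(3, -3, rep(0, 6))) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- rbinom(n, 1, plogis(drop(x %*% beta[seq_len(p)])))
  list(x = x, y = y)
}

test_that("min-max normalization learns from training rows only", {
  tab <- data.frame(split = c("training", "training", "training",
                              "validation"),
                    a = c(2, 4, 6, 8), b = c(1, 1, 1, 5))
  norm <- fit_normalizer(tab)
  out <- apply_normalizer(norm, tab)
  expect_equal(out$a, c(0, 0.5, 1, 1.5))  # validation extrapolates, unclipped
  expect_true(norm$constant[["b"]])
  expect_equal(out$b, c(0, 0, 0, 0))      # constant training column -> 0
  bad <- tab; names(bad)[2] <- "zz"
  expect_error(apply_normalizer(norm, bad), "mismatch")
  expect_error(fit_normalizer(tab[1, , drop = FALSE]), ">= 2 training rows")
})

test_that("all penalized coefficients vanish at and above lambda_max", {
  d <- make_xy()
  lmax <- max(abs(crossprod(d$x, d$y - mean(d$y)))) / length(d$y)
  fit <- lasso_logistic(d$x, d$y, lambda = c(2 * lmax, lmax))
  expect_equal(max(abs(fit$beta)), 0)
  expect_equal(fit$df, c(0, 0), ignore_attr = TRUE)
  # default grid starts at lambda_max: empty there, growing down the path
  path <- lasso_logistic(d$x, d$y)
  expect_equal(path$df[1], 0, ignore_attr = TRUE)
  expect_gte(path$df[length(path$df)], path$df[1])
})

test_that("the unpenalized limit matches an IRLS (glm) oracle", {
  d <- make_xy()
  fit <- lasso_logistic(d$x, d$y, lambda = c(1, 1e-10))
  oracle <- glm(d$y ~ d$x, family = binomial)
  expect_lt(max(abs(coef(fit, s = 1e-10) - coef(oracle))), 1e-4)
})

test_that("the path agrees with an independent solver mid-path", {
  d <- make_xy(n = 200, p = 12, beta = c(2, -2, 1.5, rep(0, 9)))
  s <- 0.02
  fit <- lasso_logistic(d$x, d$y, lambda = c(1, s))
  gn <- glmnet::glmnet(d$x, d$y, family = "binomial", lambda = s,
                       standardize = FALSE, thresh = 1e-12)
  expect_lt(max(abs(coef(fit, s = s)[-1] - as.numeric(gn$beta))), 1e-4)
})

test_that("duplicated features split weight without changing predictions", {
  d <- make_xy(n = 150, p = 4, beta = c(2.5, -2, 1, 0))
  xdup <- cbind(d$x, f01b = d$x[, 1])
  s <- 0.01
  f1 <- lasso_logistic(d$x, d$y, lambda = c(1, s))
  f2 <- lasso_logistic(xdup, d$y, lambda = c(1, s))
  p1 <- predict(f1, d$x, s = s)
  p2 <- predict(f2, xdup, s = s)
  expect_lt(max(abs(p1 - p2)), 1e-3)
  expect_lt(abs(abs(coef(f1, s)[["f01"]]) -
                (abs(coef(f2, s)[["f01"]]) + abs(coef(f2, s)[["f01b"]]))),
            1e-3)
})

test_that("solver objective is non-increasing across iterations", {
  d <- make_xy(n = 100, p = 6, beta = c(2, -1, 1, 0, 0, 0))
  for (lam in c(0.05, 0.01, 0.001)) {
    tr <- sonoradiomics:::lasso_logistic_cd_cpp(d$x, d$y, lam, 0,
                                                numeric(6), 1e-7, 1e5, TRUE)
    expect_true(all(diff(tr$objective) <= 1e-12))
  }
})

test_that("held-out deviance behaves at the grid ends and the null point", {
  # constant prediction of one half costs 2 ln 2
  expect_equal(binomial_deviance(c(0, 1, 1, 0), rep(0.5, 4)), 2 * log(2))
  # a perfectly predictive feature drives held-out deviance toward zero
  set.seed(8)
  x <- matrix(c(rep(0, 40), rep(1, 40)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- as.numeric(x[, 1] == 1)
  cv <- cv_lasso_logistic(x, y, k = 4, seed = 2, lambda = c(0.5, 1e-4))
  expect_lt(min(cv$cvm), 0.05)
  # deviance at lambda_max equals the held-out null-model deviance
  d <- make_xy()
  cv2 <- cv_lasso_logistic(d$x, d$y, k = 5, seed = 3)
  null_dev <- mean(vapply(seq_len(5), function(f) {
    tr <- cv2$fold != f
    binomial_deviance(d$y[!tr], rep(mean(d$y[tr]), sum(!tr)))
  }, numeric(1)))
  expect_equal(cv2$cvm[1], null_dev, tolerance = 1e-10)
  expect_gte(cv2$lambda_1se, cv2$lambda_min)
})

test_that("cross-validation is reproducible and stratified", {
  d <- make_xy(n = 90)
  a <- cv_lasso_logistic(d$x, d$y, k = 5, seed = 42)
  b <- cv_lasso_logistic(d$x, d$y, k = 5, seed = 42)
  expect_identical(a$fold, b$fold)
  expect_identical(a$lambda_min, b$lambda_min)
  expect_identical(a$cvm, b$cvm)
  for (f in 1:5) expect_length(unique(d$y[a$fold == f]), 2)
  # patient-grouped folds never split a group
  groups <- rep(sprintf("P%02d", 1:30), each = 3)
  g <- cv_lasso_logistic(d$x, d$y, k = 5, seed = 7, groups = groups)
  expect_true(all(tapply(g$fold, groups, function(v) length(unique(v))) == 1))
})

test_that("selection rules order and bound the reported features", {
  d <- make_xy(n = 250, p = 10, beta = c(3, -3, 2, rep(0, 7)))
  cv <- cv_lasso_logistic(d$x, d$y, k = 5, seed = 9)
  sel <- select_features(cv, rule = "lambda_min")
  expect_true(all(c("f01", "f02") %in% sel$feature))
  expect_true(all(diff(abs(sel$coefficient)) <= 1e-12))  # sorted by |beta|
  expect_equal(nrow(select_features(cv, rule = "lambda_max")), 0)
  expect_error(select_features(cv, rule = "bogus"))
  # the AUC criterion runs on the same fold machinery
  cva <- cv_lasso_logistic(d$x, d$y, k = 5, seed = 9, criterion = "auc")
  expect_identical(cva$fold, cv$fold)
  expect_true(cva$lambda_min %in% cva$lambda)
})

test_that("degenerate responses are rejected", {
  d <- make_xy()
  expect_error(lasso_logistic(d$x, rep(1, nrow(d$x))), "single class")
  expect_error(cv_lasso_logistic(d$x, d$y, k = 1), "k must be")
})
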