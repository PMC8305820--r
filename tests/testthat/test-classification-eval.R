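toy_separable <- function(n = 40, seed = 3) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n, 2, 0.3), ncol = 2),
             matrix(rnorm(n, -2, 0.3), ncol = 2))
  colnames(x) <- c("u", "v")
  y <- rep(c("MN", "IgA"), each = n / 2)
  list(x = x, y = y)
}

test_that("all four classifier kinds train and predict probabilities", {
  d <- toy_separable()
  for (kind in c("logistic_regression", "svm", "random_forest", "knn")) {
    m <- train_classifier(d$x, d$y, kind, seed = 5)
    p <- predict(m, d$x)
    expect_length(p, nrow(d$x))
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_error(train_classifier(d$x, d$y, "boosted_stump"), "unknown")
  expect_error(train_classifier(d$x[1:3, ], c("MN", "MN", "IgA")),
               ">= 2 training rows")
})

test_that("logistic regression separates a linearly separable toy set", {
  d <- toy_separable()
  m <- train_classifier(d$x, d$y, "logistic_regression")
  acc <- mean((predict(m, d$x) >= 0.5) == (d$y == "MN"))
  expect_equal(acc, 1.0)
})

test_that("knn with k equal to n predicts the training prevalence", {
  d <- toy_separable(n = 30)
  m <- train_classifier(d$x, d$y, "knn", params = list(k = nrow(d$x)))
  p <- predict(m, d$x[1:5, ])
  expect_true(all(abs(p - mean(d$y == "MN")) < 1e-12))
})

test_that("seeded training is deterministic", {
  d <- toy_separable(n = 60, seed = 8)
  for (kind in c("random_forest", "svm", "knn")) {
    a <- predict(train_classifier(d$x, d$y, kind, seed = 77), d$x)
    b <- predict(train_classifier(d$x, d$y, kind, seed = 77), d$x)
    expect_identical(a, b)
  }
})

test_that("patient aggregation is the unweighted slice mean", {
  probs <- c(0.6, 0.8, 0.7, 0.2)
  ids <- c("A", "A", "A", "B")
  agg <- aggregate_to_patients(probs, ids)
  expect_equal(unname(agg["A"]), 0.7)
  expect_equal(unname(agg["B"]), 0.2)  # single-slice patient unchanged
  perm <- sample(4)
  expect_equal(sort(aggregate_to_patients(probs[perm], ids[perm])),
               sort(agg))
  man <- data.frame(patient_id = c("A"))
  expect_error(aggregate_to_patients(probs, ids, man), "orphan")
})

test_that("trapezoidal AUC matches limits and the pairwise oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.4, 4))$auc, 0.5)
  set.seed(14)
  for (rep in 1:20) {
    n <- 200
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    expect_equal(roc_auc(y, s)$auc, brute_auc(y, s), tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), runif(5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- rbinom(150, 1, 0.5)
  s <- runif(150) + 0.5 * y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(roc_auc(y, s)$auc, ref, tolerance = 1e-12)
})

test_that("evaluation reports coherent two-granularity metrics", {
  # confusion arithmetic: 9 MN / 8 IgA patients, one error in each class
  y <- rep(c(1, 0), c(9, 8))
  p <- c(rep(0.9, 8), 0.1, rep(0.2, 7), 0.8)
  m <- sonoradiomics:::binary_metrics(y, p)
  expect_equal(m$sensitivity, 8 / 9, tolerance = 1e-12)
  expect_equal(m$specificity, 7 / 8, tolerance = 1e-12)
  expect_equal(round(m$sensitivity, 4), 0.8889)
  expect_equal(round(m$specificity, 4), 0.8750)
  expect_equal(sum(m$confusion), 17)
  expect_equal(m$accuracy, 15 / 17)

  d <- toy_separable(n = 40)
  ids <- rep(sprintf("P%02d", 1:10), each = 4)
  models <- list(lr = train_classifier(d$x, d$y, "logistic_regression"))
  rep_ <- evaluate_classifiers(models, d$x, d$y, ids)
  met <- eval_metrics(rep_)
  expect_equal(nrow(met), 2)  # one classifier, two granularities
  expect_equal(met$accuracy[met$granularity == "patient"], 1.0)
  expect_equal(met$auc[met$granularity == "slice"], 1.0)
  expect_true(all(met$tp + met$fn + met$tn + met$fp ==
                    c(rep_$n_slices, rep_$n_patients)))
  expect_error(evaluate_classifiers(models, d$x[0, ], character(0),
                                    character(0)), "empty validation")
})

test_that("patient aggregation helps when slices add independent noise", {
  gains <- vapply(1:20, function(seed) {
    tab <- latent_feature_table(seed = seed)
    x <- as.matrix(tab[, c("f1", "g1", "g2", "g3")])
    # per class: 7 training patients (42 rows) then 3 validation (18 rows)
    tr <- rep(rep(c(TRUE, FALSE), c(7 * 6, 3 * 6)), 2)
    m <- train_classifier(x[tr, ], tab$class_label[tr],
                          "logistic_regression", seed = seed)
    ev <- evaluate_classifiers(list(m), x[!tr, ], tab$class_label[!tr],
                               tab$patient_id[!tr])
    met <- eval_metrics(ev)
    met$auc[met$granularity == "patient"] -
      met$auc[met$granularity == "slice"]
  }, numeric(1))
  expect_gte(mean(gains), 0)
})

test_that("label permutation leaves validation AUC near chance", {
  inside <- vapply(1:50, function(seed) {
    tab <- latent_feature_table(n_pat_a = 30, n_pat_b = 30, slices = 2,
                                effect = 0, noise = 3, seed = 100 + seed)
    x <- as.matrix(tab[, c("f1", "g1", "g2", "g3")])
    # per class: 20 training patients (40 rows) then 10 validation (20 rows)
    tr <- rep(rep(c(TRUE, FALSE), c(40, 20)), 2)
    set.seed(seed)
    y_shuffled <- sample(tab$class_label[tr])
    m <- train_classifier(x[tr, ], y_shuffled, "logistic_regression",
                          seed = seed)
    auc <- roc_auc(tab$class_label[!tr], predict(m, x[!tr, ]))$auc
    auc >= 0.3 && auc <= 0.7
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})
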