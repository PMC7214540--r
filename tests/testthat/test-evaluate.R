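test_that("confusion metrics follow the printed formulas", {
  expect_equal(confusionMetrics(TP = 9, FN = 1, TN = 8, FP = 2),
               c(Sn = 90, Sp = 80, ACC = 85))
  expect_equal(confusionMetrics(5, 0, 7, 0),
               c(Sn = 100, Sp = 100, ACC = 100))
  # all-positive predictor on a mixed set
  expect_equal(unname(confusionMetrics(10, 0, 0, 10)["Sp"]), 0)
  # no positives at all: Sn is not applicable, not 0
  expect_true(is.na(confusionMetrics(0, 0, 5, 5)["Sn"]))
  expect_error(confusionMetrics(0, 0, 0, 0), "zero")
})

test_that("ACC is the class-size-weighted mean of Sn and Sp", {
  set.seed(14)
  for (i in 1:200) {
    cnt <- rmultinom(1, 50, runif(4, 0.05, 1))
    TP <- cnt[1]; FN <- cnt[2]; TN <- cnt[3]; FP <- cnt[4]
    if (TP + FN == 0 || TN + FP == 0) next
    m <- confusionMetrics(TP, FN, TN, FP)
    P <- TP + FN; N <- TN + FP
    expect_equal(unname(m["ACC"]),
                 unname((m["Sn"] * P + m["Sp"] * N) / (P + N)))
    expect_gte(m["ACC"], min(m["Sn"], m["Sp"]))
    expect_lte(m["ACC"], max(m["Sn"], m["Sp"]))
  }
})

test_that("ROC endpoints, perfect and reversed rankings, tie handling", {
  r <- rocCurve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))

  set.seed(15)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5)
  a <- rocCurve(s, l)$auc
  expect_equal(rocCurve(-s, l)$auc, 1 - a)
  # invariant under strictly monotone transforms of the scores
  expect_equal(rocCurve(exp(2 * s), l)$auc, a)
  # tied scores form one threshold step
  rt <- rocCurve(c(1, 1, 1, 0), c(1, 0, 1, 0))
  expect_equal(nrow(rt$points), 3L)
  expect_error(rocCurve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC area matches pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(16)
  for (i in 1:10) {
    l <- rbinom(80, 1, 0.5)
    if (length(unique(l)) < 2) next
    s <- rnorm(80) + 0.8 * l
    ours <- rocCurve(s, l)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref)
  }
})

test_that("chance-level scores give area near one half", {
  set.seed(17)
  l <- rep_len(c(1, 0), 2000)
  s <- rnorm(2000)
  expect_lt(abs(rocCurve(s, l)$auc - 0.5), 0.05)
})

test_that("cross-validation is stratified, exhaustive and deterministic", {
  set.seed(18)
  n <- 80
  labs <- rep_len(c(1L, 0L), n)
  v <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  fm <- toyFeatureMatrix(v, labels = labs)
  r1 <- crossValidate(fm, model = "svm", folds = 5, seed = 7)
  r2 <- crossValidate(fm, model = "svm", folds = 5, seed = 7)
  expect_identical(r1@metrics, r2@metrics)
  expect_identical(r1@foldCounts, r2@foldCounts)
  expect_identical(r1@roc, r2@roc)
  # each observation in exactly one test fold, class ratios within 1
  assign <- ThermoRAAC:::.stratifiedFolds(labs, 5L, 7L)
  expect_equal(sort(unique(assign)), 1:5)
  expect_equal(length(assign), n)
  for (f in 1:5) {
    expect_equal(sum(assign == f), n / 5)
    expect_lte(abs(sum(assign == f & labs == 1L) -
                   sum(assign == f) / 2), 1)
  }
  expect_equal(sum(r1@pooled), n)
  expect_error(crossValidate(fm, folds = 41, seed = 1), "fewer than")
})

test_that("well-separated point clouds are classified perfectly", {
  set.seed(19)
  n <- 200
  labs <- rep(c(1L, 0L), each = n / 2)
  v <- cbind(x = rnorm(n, mean = ifelse(labs == 1, 4, -4)),
             y = rnorm(n))
  fm <- toyFeatureMatrix(v, labels = labs)
  rep_svm <- crossValidate(fm, model = "svm", folds = 10, seed = 4)
  expect_equal(unname(rep_svm@metrics["ACC"]), 100)
  expect_equal(rep_svm@auc, 1)
})

test_that("all four classifier backends produce sane reports", {
  set.seed(20)
  n <- 60
  labs <- rep_len(c(1L, 0L), n)
  v <- cbind(s = as.numeric(labs) + rnorm(n, sd = 0.3),
             z = rnorm(n))
  fm <- toyFeatureMatrix(v, labels = labs)
  for (m in c("svm", "random_forest", "decision_tree", "naive_bayes")) {
    r <- crossValidate(fm, model = m, folds = 5, seed = 9)
    expect_s4_class(r, "EvalReport")
    expect_gte(unname(r@metrics["ACC"]), 70)
    expect_equal(sum(r@pooled), n)
    expect_equal(colSums(r@foldCounts[, c("TP", "FN", "TN", "FP")]),
                 r@pooled, ignore_attr = TRUE)
  }
  expect_error(crossValidate(fm, model = "boosting"), "unknown model")
})
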