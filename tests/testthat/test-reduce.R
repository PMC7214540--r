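test_that("min-max normalization maps columns onto [0,1]", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 0.25, 1))
  fm <- toyFeatureMatrix(m)
  expect_warning(nfm <- normalizeFeatures(fm), "constant")
  v <- featureValues(nfm)
  expect_equal(unname(v[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(v[, "b"]), c(0, 0, 0))
  expect_equal(unname(v[, "c"]), c(0, 0.25, 1))  # fixed endpoints unchanged
  expect_true(isNormalized(nfm))
})

test_that("pearsonCor implements the n-1 sample formula with conventions", {
  expect_equal(pearsonCor(c(0, 1, 2), c(0, 2, 4)), 1)
  expect_equal(pearsonCor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearsonCor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearsonCor(1:3, 1:4), "equal length")
  expect_error(pearsonCor(1, 2), "at least 2")
  expect_warning(z <- pearsonCor(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_equal(z, 0)
})

test_that("pearsonCor is symmetric, affine-invariant and bounded", {
  set.seed(12)
  for (i in 1:25) {
    x <- rnorm(20); y <- rnorm(20)
    r <- pearsonCor(x, y)
    expect_gte(r, -1); expect_lte(r, 1)
    expect_equal(pearsonCor(y, x), r)
    expect_equal(pearsonCor(3 * x + 7, y), r)
    # direct evaluation of the printed formula as an independent check
    direct <- sum((x - mean(x)) / sd(x) * (y - mean(y)) / sd(y)) /
      (length(x) - 1)
    expect_equal(r, direct)
  }
})

test_that("the rule table produces the documented D/R assignments", {
  # two identical columns -> earlier reserved, later removed
  set.seed(1)
  x <- rnorm(30)
  fm <- suppressWarnings(normalizeFeatures(toyFeatureMatrix(
    cbind(f1 = x, f2 = x, f3 = rnorm(30)))))
  pr <- correlationPrune(fm, threshold = 0.85)
  expect_equal(reservedFeatures(pr), "f1")
  expect_equal(removedFeatures(pr), "f2")

  # no high pair -> both sets empty, all features kept
  set.seed(2)
  fm0 <- suppressWarnings(normalizeFeatures(toyFeatureMatrix(
    matrix(rnorm(300), 50, 6))))
  pr0 <- correlationPrune(fm0, threshold = 0.85)
  expect_equal(length(removedFeatures(pr0)), 0L)
  expect_equal(length(reservedFeatures(pr0)), 0L)
  expect_equal(ncol(featureValues(applyPrune(fm0, pr0))), 6L)

  # chain f1~f2, f2~f3 with cor(f1,f3) below T: rules 1 then 5
  cols <- chainColumns(n = 64, rho = 0.9)
  expect_gt(abs(cor(cols[, 1], cols[, 2])), 0.85)
  expect_gt(abs(cor(cols[, 2], cols[, 3])), 0.85)
  expect_lt(abs(cor(cols[, 1], cols[, 3])), 0.85)
  fmc <- suppressWarnings(normalizeFeatures(toyFeatureMatrix(cols)))
  prc <- correlationPrune(fmc, threshold = 0.85)
  expect_equal(reservedFeatures(prc), "f1")
  expect_setequal(removedFeatures(prc), c("f2", "f3"))
  expect_equal(prc@pairs$rule, c(1L, 5L))

  expect_error(correlationPrune(toyFeatureMatrix(cols), 0.85),
               "normalized")
})

test_that("pruning is deterministic and D, R stay disjoint", {
  set.seed(8)
  base <- matrix(rnorm(200), 40, 5)
  m <- cbind(base, base[, 1:3] + 0.05 * matrix(rnorm(120), 40, 3))
  colnames(m) <- paste0("f", 1:8)
  fm <- suppressWarnings(normalizeFeatures(toyFeatureMatrix(m)))
  pr1 <- correlationPrune(fm, threshold = 0.85)
  pr2 <- correlationPrune(fm, threshold = 0.85)
  expect_identical(removedFeatures(pr1), removedFeatures(pr2))
  expect_identical(reservedFeatures(pr1), reservedFeatures(pr2))
  expect_length(intersect(removedFeatures(pr1), reservedFeatures(pr1)), 0)
  # every removed feature participates in at least one driving pair
  expect_true(all(removedFeatures(pr1) %in%
                  c(pr1@pairs$X, pr1@pairs$Y)))
})

test_that("strict mode leaves no retained pair above the threshold", {
  set.seed(99)
  for (i in 1:50) {
    n <- 30; M <- 8
    base <- matrix(rnorm(n * 3), n, 3)
    mix <- base[, sample(3, M, replace = TRUE)] +
      0.6 * matrix(rnorm(n * M), n, M)
    colnames(mix) <- paste0("f", seq_len(M))
    fm <- suppressWarnings(normalizeFeatures(toyFeatureMatrix(mix)))
    T <- 0.5
    pr <- correlationPrune(fm, threshold = T, strict = TRUE)
    kept <- applyPrune(fm, pr)
    C <- abs(cor(featureValues(kept)))
    diag(C) <- 0
    expect_lte(max(C), T + 1e-12)
  }
})
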