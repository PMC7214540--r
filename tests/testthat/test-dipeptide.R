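s19 <- builtinScheme("susko19")
id20 <- builtinScheme("identity20")

test_that("gapped dipeptide frequencies match their defining examples", {
  fm <- gappedDipeptideFeatures(ProteinSet(c(s = "AAA")), scheme = s19,
                                maxGap = 0)
  v <- featureValues(fm)[1, ]
  expect_equal(unname(v["RD|0|A|A"]), 1)
  expect_equal(sum(v != 0), 1L)

  fm1 <- gappedDipeptideFeatures(ProteinSet(c(s = "AKA")), scheme = s19,
                                 maxGap = 1)
  v1 <- featureValues(fm1)[1, ]
  expect_equal(unname(v1["RD|1|A|A"]), 1)

  fm2 <- gappedDipeptideFeatures(ProteinSet(c(s = "AKAK")), scheme = s19,
                                 maxGap = 0)
  v2 <- featureValues(fm2)[1, ]
  expect_equal(unname(v2["RD|0|A|K"]), 2 / 3)
  expect_equal(unname(v2["RD|0|K|A"]), 1 / 3)
})

test_that("original vs reduced dipeptides: IV merging and block widths", {
  ps <- ProteinSet(c(s = "IVIV"))
  orig <- featureValues(originalDipeptideFeatures(ps, maxGap = 0))[1, ]
  expect_equal(unname(orig["RD|0|I|V"]), 2 / 3)
  expect_equal(unname(orig["RD|0|V|I"]), 1 / 3)
  expect_equal(length(orig), 400L)  # 20^2 per gap block

  red <- featureValues(gappedDipeptideFeatures(ps, s19, maxGap = 0))[1, ]
  expect_equal(unname(red["RD|0|V|V"]), 1)
  expect_equal(length(red), 361L)  # 19^2 per gap block

  full <- gappedDipeptideFeatures(ProteinSet(c(s = "ACDKLMNP")), s19,
                                  maxGap = 2)
  expect_equal(ncol(featureValues(full)), 1083L)  # 3 x 361
})

test_that("counts agree exactly with the brute-force enumerator", {
  set.seed(77)
  schemes <- list(s19, id20, builtinScheme("dayhoff6"))
  for (rep in 1:200) {
    scheme <- schemes[[(rep %% 3) + 1L]]
    seq <- randomSequences(1, minLen = 3, maxLen = 50)
    red <- reduceSequence(seq, scheme)
    lambda <- (rep %% 3)
    expect_identical(dipeptideCounts(red[[1]], scheme, lambda),
                     bruteDipeptideCounts(red[[1]], scheme, lambda))
  }
})

test_that("per-gap frequency blocks sum to one whenever countable", {
  set.seed(31)
  ps <- randomProteinSet(20, minLen = 4, maxLen = 40)
  fm <- gappedDipeptideFeatures(ps, s19, maxGap = 2)
  v <- featureValues(fm)
  lam <- featureMeta(fm)$lambda
  for (l in 0:2) {
    sums <- rowSums(v[, lam == l, drop = FALSE])
    expect_equal(sums, rep(1, nrow(v)), ignore_attr = TRUE)
  }
})

test_that("sequences too short for a gap yield a zero block and a warning", {
  expect_warning(fm <- gappedDipeptideFeatures(ProteinSet(c(s = "AK")),
                                               s19, maxGap = 2),
                 "uncountable")
  v <- featureValues(fm)
  lam <- featureMeta(fm)$lambda
  expect_equal(sum(v[1, lam == 0]), 1)
  expect_equal(sum(v[1, lam >= 1]), 0)
})

test_that("identity frequencies aggregate to the reduced ones cell by cell", {
  set.seed(13)
  seqs <- randomSequences(10, minLen = 5, maxLen = 60)
  members <- strsplit(s19@groups, "")
  for (s in seqs) {
    ps <- ProteinSet(stats::setNames(s, "x"))
    vo <- featureValues(originalDipeptideFeatures(ps, maxGap = 1))[1, ]
    vr <- featureValues(gappedDipeptideFeatures(ps, s19, maxGap = 1))[1, ]
    for (l in 0:1) for (ga in c(1, 8)) for (gb in c(8, 19)) {
      cells <- as.vector(outer(members[[ga]], members[[gb]], function(a, b)
        paste("RD", l, a, b, sep = "|")))
      expect_equal(sum(vo[cells]),
                   unname(vr[paste("RD", l, s19@representatives[ga],
                                   s19@representatives[gb], sep = "|")]))
    }
  }
})
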