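test_that("the physicochemical descriptor has the 188D layout", {
  ps <- randomProteinSet(5, minLen = 10, maxLen = 80, seed = 3)
  fm <- physchem188(ps)
  expect_equal(ncol(featureValues(fm)), 188L)
  nm <- featureMeta(fm)$name
  expect_equal(sum(startsWith(nm, "PC|aac|")), 20L)
  expect_equal(sum(startsWith(nm, "PC|comp|")), 24L)
  expect_equal(sum(startsWith(nm, "PC|dist|")), 120L)
  expect_equal(sum(startsWith(nm, "PC|tr|")), 24L)
})

test_that("homopolymer AAAA fills the blocks as the conventions dictate", {
  fm <- physchem188(ProteinSet(c(s = "AAAA")))
  v <- featureValues(fm)[1, ]
  expect_equal(unname(v["PC|aac|A"]), 1)
  expect_equal(sum(v[startsWith(names(v), "PC|aac|")]), 1)
  # for every property, A's group has composition 1, the others 0
  gr <- ctdGroups()
  for (i in seq_len(nrow(gr))) {
    gA <- which(vapply(1:3, function(j)
      grepl("A", gr[i, paste0("group", j)], fixed = TRUE), logical(1)))
    comp <- v[paste("PC|comp", gr$property[i], paste0("g", 1:3), sep = "|")]
    expect_equal(unname(comp[gA]), 1)
    expect_equal(sum(comp), 1)
    # distribution of A's group: 1st/25/50/75/100 occurrence convention
    distr <- v[paste("PC|dist", gr$property[i], paste0("g", gA),
                     c("first", "p25", "p50", "p75", "p100"), sep = "|")]
    expect_equal(unname(distr), c(0.25, 0.25, 0.5, 0.75, 1.0))
  }
  expect_equal(sum(v[startsWith(names(v), "PC|tr|")]), 0)
})

test_that("composition triples sum to one and AAC is reversal-invariant", {
  ps <- randomProteinSet(8, minLen = 6, maxLen = 60, seed = 9)
  v <- featureValues(physchem188(ps))
  expect_equal(rowSums(v[, startsWith(colnames(v), "PC|aac|")]),
               rep(1, nrow(v)), ignore_attr = TRUE)
  for (p in ctdGroups()$property)
    expect_equal(rowSums(v[, paste("PC|comp", p, paste0("g", 1:3),
                                   sep = "|")]),
                 rep(1, nrow(v)), ignore_attr = TRUE)
  seqs <- as.character(sequences(ps))
  rev_seqs <- vapply(strsplit(seqs, ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
  vr <- featureValues(physchem188(ProteinSet(
    stats::setNames(rev_seqs, names(seqs)))))
  aac <- startsWith(colnames(v), "PC|aac|")
  expect_equal(v[, aac], vr[, aac])
})

test_that("transition counts match a hand count", {
  # hydrophobicity groups: g1 = RKEDQN, g2 = GASTPHY, g3 = CLVIMFW
  v <- featureValues(physchem188(ProteinSet(c(s = "ARAC"))))[1, ]
  # adjacent pairs: A-R (g2,g1), R-A (g1,g2), A-C (g2,g3) over L-1 = 3
  expect_equal(unname(v["PC|tr|hydrophobicity|g1g2"]), 2 / 3)
  expect_equal(unname(v["PC|tr|hydrophobicity|g2g3"]), 1 / 3)
  expect_equal(unname(v["PC|tr|hydrophobicity|g1g3"]), 0)
})

test_that("ACC features follow the lagged-covariance formula", {
  # a single unstandardized scale mapping A,C,D,E -> 1,2,3,4 gives the
  # direct hand evaluation 1.25/3 at lag 1
  sc <- matrix(0, 20, 1, dimnames = list(ThermoRAAC:::AA20, "toy"))
  sc[c("A", "C", "D", "E"), 1] <- 1:4
  fm <- accFeatures(ProteinSet(c(s = "ACDE")), lg = 2, scales = sc)
  v <- featureValues(fm)[1, ]
  expect_equal(unname(v["ACC|AC|toy|1"]), 1.25 / 3)
  # lag 2: [(-1.5)(0.5) + (-0.5)(1.5)] / 2
  expect_equal(unname(v["ACC|AC|toy|2"]), -1.5 / 2)
})

test_that("ACC dimensionality, homopolymer zeros and reversal invariance", {
  fm <- accFeatures(ProteinSet(c(s = "KLMNPQRST")))
  expect_equal(ncol(featureValues(fm)), 18L)  # N*lg + N*(N-1)*lg, N=3 lg=2
  hom <- featureValues(accFeatures(ProteinSet(c(s = strrep("K", 30)))))
  expect_equal(max(abs(hom)), 0)
  seqs <- randomSequences(5, minLen = 10, maxLen = 40, seed = 17)
  for (s in seqs) {
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    ac_cols <- 1:6  # AC block
    a <- featureValues(accFeatures(ProteinSet(c(x = s))))[1, ac_cols]
    b <- featureValues(accFeatures(ProteinSet(c(x = rev_s))))[1, ac_cols]
    expect_equal(a, b)
  }
  expect_error(accFeatures(ProteinSet(c(s = "AK")), lg = 2), "too short")
})

test_that("ACC property scales are standardized over the 20 residues", {
  sc <- accScales()
  expect_equal(colMeans(sc), rep(0, 3), ignore_attr = TRUE)
  expect_equal(apply(sc, 2, sd), rep(1, 3), ignore_attr = TRUE)
})
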