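test_that("generation respects counts, labels and the length range", {
  spec <- generatorSpec(5, 3, lengthRange = c(50, 80), delta = 0.02,
                        seed = 2)
  ps <- generateProteins(spec)
  expect_equal(length(ps), 8L)
  expect_equal(nPositive(ps), 5L)
  expect_equal(nNegative(ps), 3L)
  w <- Biostrings::width(sequences(ps))
  expect_true(all(w >= 50 & w <= 80))
})

test_that("the same spec and seed give byte-identical FASTA output", {
  spec <- generatorSpec(4, 4, c(40, 60), delta = 0.03, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  generateProteins(spec, fastaPath = f1)
  generateProteins(spec, fastaPath = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("tilts that leave the simplex are rejected before generation", {
  expect_error(generatorSpec(2, 2, delta = 0.09), "negative")
  # delta = 0.08 is the boundary of the default base composition
  expect_silent(generatorSpec(2, 2, delta = 0.08))
})

test_that("delta = 0 classes are compositionally indistinguishable", {
  spec <- generatorSpec(60, 60, c(100, 200), delta = 0, seed = 23)
  ps <- generateProteins(spec)
  seqs <- as.character(sequences(ps))
  countsFor <- function(idx) {
    ch <- unlist(strsplit(seqs[idx], ""))
    tabulate(match(ch, ThermoRAAC:::AA20), nbins = 20)
  }
  tab <- rbind(countsFor(labels(ps) == 1L), countsFor(labels(ps) == 0L))
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("empirical composition converges to the class composition", {
  # ~1e6 residues in the positive class
  spec <- generatorSpec(2000, 1, lengthRange = c(500, 500), delta = 0.04,
                        seed = 31)
  ps <- generateProteins(spec)
  seqs <- as.character(sequences(ps))[labels(ps) == 1L]
  ch <- unlist(strsplit(seqs, ""))
  expect_gte(length(ch), 1e6)
  emp <- tabulate(match(ch, ThermoRAAC:::AA20), nbins = 20) / length(ch)
  expect_lt(sum(abs(emp - classComposition(spec, 1L))), 0.01)
})

test_that("class compositions carry the promised tilts", {
  spec <- generatorSpec(1, 1, delta = 0.05, seed = 1)
  pos <- classComposition(spec, 1L)
  neg <- classComposition(spec, 0L)
  for (r in c("K", "R", "E")) expect_gt(pos[r], neg[r])
  for (r in c("Q", "M")) expect_lt(pos[r], neg[r])
  expect_equal(sum(pos), 1)
  expect_equal(sum(neg), 1)
})

test_that("the analytic separability estimate tracks simulation", {
  spec0 <- generatorSpec(1, 1, delta = 0, seed = 1)
  expect_equal(expectedSeparation(spec0), 50)
  specMax <- generatorSpec(1, 1, delta = 0.08, lengthRange = c(400, 600),
                           seed = 1)
  expect_gt(expectedSeparation(specMax), 99)

  # Monte-Carlo check at an intermediate delta: classify sequences by the
  # sign of the exact log-likelihood ratio and compare accuracies
  spec <- generatorSpec(300, 300, lengthRange = c(150, 250), delta = 0.01,
                        seed = 41)
  ps <- generateProteins(spec)
  llr <- log(classComposition(spec, 1L) / classComposition(spec, 0L))
  seqs <- as.character(sequences(ps))
  scores <- vapply(seqs, function(s)
    sum(llr[strsplit(s, "")[[1]]]), numeric(1))
  acc <- mean((scores > 0) == (labels(ps) == 1L)) * 100
  expect_lt(abs(expectedSeparation(spec) - acc), 5)
})
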