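# Shared fixtures and independent brute-force oracles.

# random valid protein sequences as a named character vector
randomSequences <- function(n, minLen = 3, maxLen = 50, seed = NULL,
                            alphabet = ThermoRAAC:::AA20) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(minLen:maxLen, n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("s", seq_len(n))
  seqs
}

randomProteinSet <- function(n, minLen = 3, maxLen = 50, seed = NULL) {
  seqs <- randomSequences(n, minLen, maxLen, seed)
  ProteinSet(seqs, labels = rep_len(c(1L, 0L), n))
}

# O(L * maxGap) brute-force gapped dipeptide counter, independent of the
# package's tabulate-based path: literal double loop over positions.
bruteDipeptideCounts <- function(sequence, scheme, lambda) {
  reps <- scheme@representatives
  k <- length(reps)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  y <- matrix(0L, k, k, dimnames = list(reps, reps))
  L <- length(ch)
  if (L - 1L - lambda >= 1L) {
    for (i in seq_len(L - 1L - lambda)) {
      a <- ch[i]; b <- ch[i + 1L + lambda]
      y[a, b] <- y[a, b] + 1L
    }
  }
  out <- integer(k * k)
  names(out) <- paste("RD", lambda, rep(reps, each = k),
                      rep(reps, times = k), sep = "|")
  for (a in seq_len(k)) for (b in seq_len(k))
    out[(a - 1L) * k + b] <- y[a, b]
  out
}

# brute-force MRMD scores: literal per-feature loops over the definition
bruteMrmd <- function(values, labels) {
  M <- ncol(values)
  MR <- MD <- numeric(M)
  for (i in seq_len(M)) {
    MR[i] <- abs(cor(values[, i], as.numeric(labels)))
    dsum <- 0
    for (j in seq_len(M)) if (j != i)
      dsum <- dsum + sqrt(sum((values[, i] - values[, j])^2))
    MD[i] <- dsum / (M - 1)
  }
  total <- MR + MD
  ord <- order(-total, colnames(values))
  data.frame(name = colnames(values)[ord], MR = MR[ord], MD = MD[ord],
             total = total[ord], stringsAsFactors = FALSE)
}

# a FeatureMatrix wrapping plain numeric columns, for reduction-stage tests
toyFeatureMatrix <- function(values, labels = NULL, normalized = FALSE) {
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (is.null(labels)) labels <- rep(NA_integer_, nrow(values))
  ThermoRAAC:::.FeatureMatrix(values, family = "physchem188",
                              labels = labels, normalized = normalized)
}

# three columns with pairwise correlations cor(f1,f2) = cor(f2,f3) = rho
# and cor(f1,f3) = rho^2 exactly (orthogonal noise construction)
chainColumns <- function(n = 64, rho = 0.9) {
  b <- sin(seq_len(n)); b <- (b - mean(b)) / sd(b)
  u1 <- rep_len(c(1, -1), n); u1 <- residuals(lm(u1 ~ b)); u1 <- u1 / sd(u1)
  u2 <- cos(seq_len(n) * 2); u2 <- residuals(lm(u2 ~ b + u1))
  u2 <- u2 / sd(u2)
  a <- sqrt(1 / rho^2 - 1)
  cbind(f1 = b + a * u1, f2 = b, f3 = b + a * u2)
}
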