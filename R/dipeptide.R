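#' @include AllClasses.R alphabet.R featureMatrix.R
NULL

#' Gapped dipeptide counts for one reduced sequence
#'
#' Counts ordered residue pairs separated by exactly `lambda` intervening
#' positions: `y(lambda, a, b)` is the number of positions `i` with
#' `s[i] = a` and `s[i + 1 + lambda] = b`. The total over all pair types is
#' `max(L - 1 - lambda, 0)`.
#'
#' @param sequence One sequence (character scalar) over the scheme's
#'   representative symbols.
#' @param scheme A [ReductionScheme-class].
#' @param lambda Gap size (0 = adjacent pair).
#' @return Named integer vector of length `k^2` in feature order (first
#'   symbol major, second minor, scheme group order).
#' @examples
#' sc <- builtinScheme("susko19")
#' counts <- dipeptideCounts("AKAK", sc, lambda = 0)
#' counts[counts > 0]
#' @export
dipeptideCounts <- function(sequence, scheme, lambda) {
  reps <- scheme@representatives
  k <- length(reps)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  idx <- match(ch, reps)
  if (anyNA(idx))
    stop("symbol '", ch[which(is.na(idx))[1L]],
         "' is not a representative of scheme '", scheme@name, "'")
  L <- length(ch)
  n_pairs <- L - 1L - lambda
  nm <- paste("RD", lambda, rep(reps, each = k), rep(reps, times = k),
              sep = "|")
  if (n_pairs < 1L) {
    y <- integer(k * k)
    names(y) <- nm
    return(y)
  }
  i1 <- idx[seq_len(n_pairs)]
  i2 <- idx[seq_len(n_pairs) + 1L + lambda]
  # tabulate in column-major (second-symbol-major) order, then transpose
  # into the row-major feature order
  v <- tabulate(i1 + k * (i2 - 1L), nbins = k * k)
  y <- as.integer(t(matrix(v, nrow = k)))
  names(y) <- nm
  y
}

#' Gapped dipeptide frequency features over a reduced alphabet
#'
#' For each gap lambda in `0..maxGap`, computes the `k^2` dipeptide
#' frequencies `f(j) = y(j) / sum_j y(j)` with the denominator taken within
#' that lambda block (it equals `L - 1 - lambda`). Sequences too short for
#' a given lambda yield an all-zero block and a warning, keeping the matrix
#' rectangular. Under the default Susko 19-letter scheme with
#' `maxGap = 2` the family contributes `3 * 361 = 1083` features.
#'
#' Feature names follow `RD|lambda|a|b`; columns are ordered lambda
#' ascending, then first symbol, then second symbol, in the scheme's
#' declared group order.
#'
#' @param x A [ProteinSet-class] (sequences are reduced internally) or a
#'   named character vector of already-reduced sequences.
#' @param scheme A [ReductionScheme-class].
#' @param maxGap Largest gap lambda (default 2).
#' @return A [FeatureMatrix-class] with `length(x)` rows and
#'   `k^2 * (maxGap + 1)` columns, family `"dipeptide"`.
#' @examples
#' ps <- ProteinSet(c(s1 = "IVIV"), labels = 1)
#' fm <- gappedDipeptideFeatures(ps)
#' featureValues(fm)[1, "RD|0|V|V"]  # 1: all pairs collapse to VV
#' @export
gappedDipeptideFeatures <- function(x, scheme = builtinScheme("susko19"),
                                    maxGap = 2L) {
  maxGap <- as.integer(maxGap)
  stopifnot(maxGap >= 0L)
  if (is(x, "ProteinSet")) {
    seqs <- reduceSequence(x, scheme)
    labs <- x@labels
  } else {
    seqs <- x
    labs <- rep(NA_integer_, length(x))
  }
  k <- length(scheme@representatives)
  lambdas <- 0L:maxGap
  ncolTotal <- k * k * length(lambdas)
  values <- matrix(0, nrow = length(seqs), ncol = ncolTotal)
  nm <- character(0)
  short <- 0L
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    block <- (li - 1L) * k * k + seq_len(k * k)
    for (si in seq_along(seqs)) {
      y <- dipeptideCounts(seqs[[si]], scheme, lam)
      tot <- sum(y)
      if (tot == 0L) short <- short + 1L
      else values[si, block] <- y / tot
      if (si == 1L) nm <- c(nm, names(y))
    }
  }
  if (short > 0L)
    warning(short, " sequence/gap block(s) too short to count; ",
            "left as all-zero (uncountable)")
  colnames(values) <- nm
  rownames(values) <- names(seqs)
  .FeatureMatrix(values, family = "dipeptide",
                 lambda = rep(lambdas, each = k * k), labels = labs)
}

#' Dipeptide frequencies over the original 20-letter alphabet
#'
#' The ablation arm: identical to [gappedDipeptideFeatures()] with the
#' identity scheme, giving `20^2 = 400` types per gap (1200 features for
#' gaps 0..2) instead of the reduced 361.
#'
#' @inheritParams gappedDipeptideFeatures
#' @return A [FeatureMatrix-class], family `"dipeptide"`.
#' @export
originalDipeptideFeatures <- function(x, maxGap = 2L) {
  gappedDipeptideFeatures(x, scheme = builtinScheme("identity20"),
                          maxGap = maxGap)
}
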