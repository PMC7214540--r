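#' @include AllClasses.R featureMatrix.R
NULL

#' Fit a PCA model truncated by cumulative contribution
#'
#' Centers the columns, decomposes the centered data by SVD, and retains
#' the smallest number of components k whose cumulative eigenvalue share
#' \deqn{\rho_k = \sum_{i \le k} \lambda_i / \sum_i \lambda_i}
#' reaches the contribution threshold T' (or a caller-fixed k). Axis signs
#' follow a fixed convention (each axis's largest-magnitude loading is
#' positive) so projections are deterministic.
#'
#' @param x A [FeatureMatrix-class] (or numeric matrix) with >= 2 rows.
#' @param threshold Cumulative contribution threshold T' in (0, 1],
#'   default 0.95.
#' @param kOverride Fix the retained component count instead of using the
#'   threshold.
#' @return A [PCAModel-class].
#' @examples
#' m <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
#' pcaFit(m, threshold = 0.95)
#' @export
pcaFit <- function(x, threshold = 0.95, kOverride = NULL) {
  v <- if (is(x, "FeatureMatrix")) x@values else as.matrix(x)
  n <- nrow(v)
  stopifnot(n >= 2L, threshold > 0, threshold <= 1)
  center <- colMeans(v)
  vc <- sweep(v, 2L, center)
  sv <- svd(vc)
  ev <- sv$d^2 / (n - 1L)
  tol <- max(sv$d) * max(dim(v)) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (rank == 0L) stop("matrix has rank 0: no principal components")
  # fixed sign convention: largest-|loading| positive per axis
  rot <- sv$v
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    lead <- which.max(abs(rot[, j]))
    rot[lead, j] < 0
  }, logical(1))
  rot[, flip] <- -rot[, flip]
  cum <- cumsum(ev) / sum(ev)
  if (!is.null(kOverride)) {
    k <- as.integer(kOverride)
    if (k > rank)
      stop("kOverride (", k, ") exceeds the data rank (", rank, ")")
    threshold <- NA_real_
  } else {
    k <- which(cum >= threshold - 1e-12)[1L]
  }
  rownames(rot) <- colnames(v)
  colnames(rot) <- paste0("PC", seq_len(ncol(rot)))
  new("PCAModel", center = center, rotation = rot, eigenvalues = ev,
      k = k, threshold = threshold, cumContribution = cum)
}

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d of %d components retained (%s)\n",
              object@k, ncol(object@rotation),
              if (is.na(object@threshold))
                "k fixed by caller"
              else sprintf("cumulative contribution %.3f >= T' = %g",
                           object@cumContribution[object@k],
                           object@threshold)))
})

#' Project data onto the retained principal axes
#'
#' @param model A [PCAModel-class].
#' @param x A [FeatureMatrix-class] or numeric matrix with the same
#'   feature columns the model was fitted on.
#' @return An n x k component matrix; when `x` is a `FeatureMatrix`, a
#'   [FeatureMatrix-class] with family `"pca"` carrying the labels through.
#' @export
pcaTransform <- function(model, x) {
  v <- if (is(x, "FeatureMatrix")) x@values else as.matrix(x)
  if (ncol(v) != nrow(model@rotation))
    stop("feature count (", ncol(v), ") does not match the model (",
         nrow(model@rotation), ")")
  scores <- sweep(v, 2L, model@center) %*%
    model@rotation[, seq_len(model@k), drop = FALSE]
  if (is(x, "FeatureMatrix"))
    return(.FeatureMatrix(scores, family = "pca", labels = x@labels))
  scores
}
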