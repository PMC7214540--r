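#' @include AllClasses.R featureMatrix.R
NULL

#' Min-max normalization of a feature matrix
#'
#' Maps every non-constant column onto [0, 1] by
#' `(x - x_min) / (x_max - x_min)`; constant columns become all-zero with
#' a warning. Normalization is a stated precondition of the correlation
#' pruning stage and makes the MRMD relevance and distance terms
#' commensurate.
#'
#' @param x A [FeatureMatrix-class].
#' @return The normalized [FeatureMatrix-class] (flag set).
#' @examples
#' m <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "f"))
#' featureValues(normalizeFeatures(
#'   ThermoRAAC:::.FeatureMatrix(m, "physchem188")))
#' @export
normalizeFeatures <- function(x) {
  stopifnot(is(x, "FeatureMatrix"), nrow(x@values) >= 1L)
  v <- x@values
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) {
    warning(sum(const), " constant column(s) mapped to all-zero")
    rng[const] <- 1
  }
  v <- sweep(sweep(v, 2L, lo), 2L, rng, "/")
  v[, const] <- 0
  initialize(x, values = v, normalized = TRUE)
}

#' Sample Pearson correlation with degenerate-input convention
#'
#' The n-1 sample convention. If either vector has zero variance the
#' correlation is undefined; 0 is returned with a warning so that
#' constant (degenerate) feature columns never drive pruning decisions.
#'
#' @param x,y Equal-length numeric vectors, n >= 2.
#' @return Correlation in [-1, 1].
#' @examples
#' pearsonCor(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance vector: correlation set to 0 by convention")
    return(0)
  }
  stats::cor(x, y)
}

# Full correlation matrix with the zero-variance convention (no warning
# spam; constant columns simply correlate 0 with everything).
.corMatrix <- function(v) {
  sds <- apply(v, 2L, stats::sd)
  C <- suppressWarnings(stats::cor(v))
  C[is.na(C)] <- 0
  diag(C) <- 1
  C[sds == 0, ] <- 0
  C[, sds == 0] <- 0
  C
}

#' Rule-based correlation pruning
#'
#' Enumerates unordered feature pairs in canonical order (upper triangle,
#' row-major) and, for every pair (X, Y) with `|rho| > threshold`, applies
#' the five-rule assignment table building a removed set D and a reserved
#' set R:
#' \enumerate{
#'   \item both unassigned: X joins R, Y joins D;
#'   \item X unassigned, Y in D: X joins R;
#'   \item X unassigned, Y in R: X joins D;
#'   \item X in R, Y unassigned: Y joins D;
#'   \item X in D, Y unassigned: Y joins D.
#' }
#' Pairs whose members are both already assigned are recorded but trigger
#' no rule. The rule table alone does not guarantee that no two reserved
#' features stay correlated; with `strict = TRUE` an extra ordered pass
#' moves the later member of any still-correlated reserved pair to D.
#' Features appearing in no high-correlation pair are implicitly kept
#' (neither in D nor in R).
#'
#' @param x A normalized [FeatureMatrix-class].
#' @param threshold Correlation threshold T in (0, 1], default 0.85.
#' @param strict Apply the reserved-pair clean-up pass (default `FALSE`,
#'   the literal rule table).
#' @return A [PruneResult-class].
#' @seealso [applyPrune()]
#' @export
correlationPrune <- function(x, threshold = 0.85, strict = FALSE) {
  stopifnot(is(x, "FeatureMatrix"))
  if (!x@normalized)
    stop("feature matrix must be normalized before correlation pruning")
  stopifnot(threshold > 0, threshold <= 1)
  v <- x@values
  nm <- colnames(v)
  M <- ncol(v)
  C <- .corMatrix(v)
  hi <- abs(C) > threshold
  hi[lower.tri(hi, diag = TRUE)] <- FALSE
  idx <- which(hi, arr.ind = TRUE)
  # canonical order: row-major over the upper triangle (by X, then Y)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]

  status <- integer(M)  # 0 unassigned, 1 reserved (R), 2 removed (D)
  rule <- integer(nrow(idx))
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1L]; j <- idx[p, 2L]
    sx <- status[i]; sy <- status[j]
    if (sx == 0L && sy == 0L) {
      status[i] <- 1L; status[j] <- 2L; rule[p] <- 1L
    } else if (sx == 0L && sy == 2L) {
      status[i] <- 1L; rule[p] <- 2L
    } else if (sx == 0L && sy == 1L) {
      status[i] <- 2L; rule[p] <- 3L
    } else if (sx == 1L && sy == 0L) {
      status[j] <- 2L; rule[p] <- 4L
    } else if (sx == 2L && sy == 0L) {
      status[j] <- 2L; rule[p] <- 5L
    }  # both assigned: recorded, no action (rule 0)
  }
  pairs <- data.frame(X = nm[idx[, 1L]], Y = nm[idx[, 2L]],
                      rho = C[idx], rule = rule,
                      stringsAsFactors = FALSE)
  if (strict && nrow(idx) > 0L) {
    for (p in seq_len(nrow(idx))) {
      i <- idx[p, 1L]; j <- idx[p, 2L]
      if (status[i] == 1L && status[j] == 1L) {
        status[j] <- 2L
        pairs <- rbind(pairs, data.frame(X = nm[i], Y = nm[j],
                                         rho = C[i, j], rule = 6L))
      }
    }
  }
  new("PruneResult", removed = nm[status == 2L], reserved = nm[status == 1L],
      threshold = threshold, strict = strict, pairs = pairs)
}

#' @rdname removedFeatures
#' @export
setMethod("removedFeatures", "PruneResult", function(x) x@removed)

#' @rdname reservedFeatures
#' @export
setMethod("reservedFeatures", "PruneResult", function(x) x@reserved)

setMethod("show", "PruneResult", function(object) {
  cat(sprintf(
    "PruneResult (T = %g%s): %d removed, %d reserved, %d driving pairs\n",
    object@threshold, if (object@strict) ", strict" else "",
    length(object@removed), length(object@reserved), nrow(object@pairs)))
})

#' Drop the pruned columns from a feature matrix
#'
#' @param x The [FeatureMatrix-class] the prune was computed on.
#' @param prune A [PruneResult-class].
#' @return `x` without the columns in the removed set D.
#' @export
applyPrune <- function(x, prune) {
  keep <- setdiff(colnames(x@values), prune@removed)
  x[, keep]
}

#' Serialize a prune result to CSV
#'
#' One row per feature that participated in a high-correlation pair, with
#' its D/R status, plus the driving pair list.
#'
#' @param prune A [PruneResult-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writePruneCSV <- function(prune, path) {
  status <- rbind(
    data.frame(feature = prune@removed, status = "removed"),
    data.frame(feature = prune@reserved, status = "reserved"))
  utils::write.csv(merge(status, prune@pairs, by.x = "feature", by.y = "X",
                         all.x = TRUE),
                   path, row.names = FALSE)
  invisible(path)
}
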