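#' @include AllClasses.R reduce.R
NULL

#' MRMD feature ranking (max relevance, max distance)
#'
#' Scores every feature by the sum of a relevance term
#' `MR_i = |pearson(F_i, C)|` (C the 0/1 class vector as reals) and a
#' non-redundancy term `MD_i`, the mean Euclidean distance between feature
#' column i and every other feature column. Features are ranked by
#' `MR_i + MD_i` descending, ties broken by feature name ascending.
#' Computed on normalized columns so the two terms share a scale origin.
#'
#' @param x A normalized, labelled [FeatureMatrix-class] with >= 2
#'   features.
#' @return A [S4Vectors::DataFrame-class] with columns `name`, `MR`, `MD`,
#'   `total`, sorted by `total` descending.
#' @seealso [mrmdSelect()]
#' @export
mrmdRank <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  v <- x@values
  if (ncol(v) < 2L)
    stop("MRMD distance term needs at least 2 features")
  labs <- x@labels
  if (anyNA(labs))
    stop("MRMD relevance term needs labels on every sample")
  cl <- as.numeric(labs)
  sds <- apply(v, 2L, stats::sd)
  MR <- abs(suppressWarnings(as.vector(stats::cor(v, cl))))
  MR[is.na(MR) | sds == 0] <- 0
  D <- as.matrix(stats::dist(t(v)))
  MD <- rowSums(D) / (ncol(v) - 1L)
  total <- MR + MD
  ord <- order(-total, colnames(v))
  DataFrame(name = colnames(v)[ord], MR = MR[ord], MD = MD[ord],
            total = total[ord])
}

#' Accuracy-driven truncation of the MRMD ranking
#'
#' Walks down the MRMD ranking evaluating the cross-validated accuracy of
#' a classifier on the top-k features for growing k, and returns the
#' smallest evaluated k achieving the maximum observed accuracy, with the
#' full (k, ACC) trace. Three sweep schedules are offered:
#' \describe{
#'   \item{`"grid"` (default)}{every k up to 20, then geometrically spaced
#'     k (factor 1.25) up to M; `patience` counts non-improving grid
#'     steps. The accuracy trace is smooth in k, so the geometric grid
#'     locates the accuracy plateau at a fraction of the dense-sweep
#'     cost.}
#'   \item{`"sweep"`}{every k = 1..M (the literal stop-at-maximum
#'     reading).}
#'   \item{`"patience"`}{dense k but stopping after `patience`
#'     consecutive non-improving k.}
#' }
#'
#' @param x The normalized, labelled [FeatureMatrix-class] the ranking was
#'   computed on.
#' @param ranking Output of [mrmdRank()] (computed here when `NULL`).
#' @param model Classifier evaluated on each subset (see
#'   [crossValidate()]); default `"svm"`.
#' @param folds Cross-validation folds for the internal evaluator.
#' @param seed Seed for the internal fold assignment.
#' @param mode `"grid"` (default), `"sweep"` or `"patience"`.
#' @param patience Non-improving evaluation steps tolerated before the
#'   walk stops early (grid/patience modes). The default `Inf` evaluates
#'   the whole schedule and returns the global maximum, since the
#'   accuracy trace can dip locally before informative features enter.
#' @return A list with `k`, `features` (selected names in rank order),
#'   `acc` (the selected accuracy, percent) and `trace`
#'   (`data.frame(k, acc)`).
#' @export
mrmdSelect <- function(x, ranking = NULL, model = "svm", folds = 5L,
                       seed = 1L, mode = c("grid", "sweep", "patience"),
                       patience = Inf) {
  mode <- match.arg(mode)
  stopifnot(is(x, "FeatureMatrix"))
  if (is.null(ranking)) ranking <- mrmdRank(x)
  nm <- ranking$name
  if (!all(nm %in% colnames(x@values)))
    stop("ranking does not match the feature matrix columns")
  M <- length(nm)
  if (M == 1L)
    return(list(k = 1L, features = nm, acc = NA_real_,
                trace = data.frame(k = integer(), acc = numeric())))
  ks <- seq_len(M)
  if (mode == "grid" && M > 20L) {
    geom <- unique(as.integer(round(20 * 1.25^seq_len(
      ceiling(log(M / 20) / log(1.25))))))
    ks <- c(1:20, pmin(geom, M))
    ks <- unique(ks[ks <= M])
  }
  trace <- data.frame(k = integer(), acc = numeric())
  best <- -Inf; bestK <- 0L; sinceBest <- 0L
  for (k in ks) {
    rep_k <- tryCatch(
      crossValidate(x[, nm[seq_len(k)]], model = model, folds = folds,
                    seed = seed),
      error = function(e) {
        cnd <- simpleError(paste0("evaluator failed at k = ", k, ": ",
                                  conditionMessage(e)))
        cnd$trace <- trace
        stop(cnd)
      })
    acc <- unname(rep_k@metrics["ACC"])
    trace <- rbind(trace, data.frame(k = k, acc = acc))
    if (acc > best + 1e-12) {
      best <- acc; bestK <- k; sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
    }
    if (mode != "sweep" && sinceBest >= patience) break
  }
  list(k = bestK, features = nm[seq_len(bestK)], acc = best, trace = trace)
}
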