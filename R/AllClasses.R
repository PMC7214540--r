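#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

# The 20 standard residues, in the canonical order used by every descriptor
# block in this package.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Labelled protein sequence dataset
#'
#' A thin S4 container pairing an [Biostrings::AAStringSet-class] of
#' validated protein sequences with an optional binary class label per
#' record. The convention throughout the package is label 1 = thermophilic
#' (positive class), 0 = non-thermophilic, `NA` = unlabelled.
#'
#' @slot sequences An `AAStringSet`; every sequence is non-empty, uppercase
#'   and restricted to the 20 standard residues; names are the unique record
#'   identifiers.
#' @slot labels Integer vector parallel to `sequences` with values 0, 1 or
#'   `NA`.
#'
#' @seealso [readFastaProteins()], [sampleBalanced()], [generateProteins()]
#' @export
setClass("ProteinSet",
  representation(sequences = "AAStringSet", labels = "integer"))

setValidity("ProteinSet", function(object) {
  msgs <- character()
  ids <- names(object@sequences)
  n <- length(object@sequences)
  if (is.null(ids) && n > 0L)
    msgs <- c(msgs, "sequences must be named with record ids")
  if (!is.null(ids)) {
    if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicate record id: %s",
                              ids[anyDuplicated(ids)]))
    if (any(!nzchar(ids)))
      msgs <- c(msgs, "record ids must be non-empty")
  }
  if (length(object@labels) != n)
    msgs <- c(msgs, "labels must be parallel to sequences")
  if (!all(object@labels %in% c(0L, 1L, NA_integer_)))
    msgs <- c(msgs, "labels must be 0, 1 or NA")
  if (n > 0L) {
    if (any(Biostrings::width(object@sequences) < 1L))
      msgs <- c(msgs, "sequences must have length >= 1")
    bad <- .invalidResidues(as.character(object@sequences))
    if (length(bad) > 0L)
      msgs <- c(msgs, sprintf("record '%s' contains invalid residue '%s'",
                              ids[bad[[1L]]["record"]], bad[[1L]]["residue"]))
  }
  if (length(msgs)) msgs else TRUE
})

# Locate residues outside the 20-letter alphabet; returns a list of
# c(record = i, residue = ch) hits (empty when clean).
.invalidResidues <- function(seqs) {
  hits <- list()
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    off <- setdiff(unique(ch), AA20)
    if (length(off) > 0L)
      hits[[length(hits) + 1L]] <- c(record = i, residue = off[[1L]])
  }
  hits
}

#' Reduced amino acid alphabet scheme
#'
#' A named partition of the 20 standard amino acids into k disjoint,
#' jointly exhaustive groups, each with one representative symbol drawn
#' from the group. Built-in schemes: `susko19` (Ile and Val merged,
#' representative V), `dayhoff6` (AGPST | DENQ | HKR | ILMV | FWY | C) and
#' `identity20`.
#'
#' @slot name Scheme name.
#' @slot groups Character vector, one string of concatenated residues per
#'   group, in declared order.
#' @slot representatives Character vector parallel to `groups`; each
#'   representative is a member of its group.
#'
#' @seealso [builtinScheme()], [readSchemeFile()], [reduceSequence()]
#' @export
setClass("ReductionScheme",
  representation(name = "character", groups = "character",
                 representatives = "character"))

setValidity("ReductionScheme", function(object) {
  msgs <- character()
  members <- strsplit(object@groups, "", fixed = TRUE)
  all_members <- unlist(members)
  if (anyDuplicated(all_members))
    msgs <- c(msgs, "groups must be disjoint")
  if (!setequal(all_members, AA20))
    msgs <- c(msgs, "groups must cover exactly the 20 standard amino acids")
  if (length(object@representatives) != length(object@groups))
    msgs <- c(msgs, "one representative per group required")
  else {
    ok <- mapply(function(rep, grp) rep %in% grp, object@representatives,
                 members)
    if (!all(ok))
      msgs <- c(msgs, "each representative must belong to its group")
    if (anyDuplicated(object@representatives))
      msgs <- c(msgs, "representatives must be distinct")
  }
  if (length(msgs)) msgs else TRUE
})

#' Sample-by-feature matrix with per-column metadata
#'
#' Numeric matrix of descriptor values (samples in rows, features in
#' columns) carrying per-feature metadata (name, family, gap index where
#' applicable), per-row binary labels, and a flag recording whether min-max
#' normalization has been applied.
#'
#' @slot values Numeric matrix, no missing values, unique column names.
#' @slot featureMeta `DataFrame` with columns `name`, `family`
#'   (one of `"physchem188"`, `"dipeptide"`, `"acc"`, `"pca"`), `lambda`
#'   (integer, `NA` outside the dipeptide family).
#' @slot labels Integer vector of row labels (0/1/NA).
#' @slot normalized Logical flag; when `TRUE` every column lies in [0, 1].
#'
#' @seealso [extractFeatures()], [normalizeFeatures()], [correlationPrune()]
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", featureMeta = "DataFrame",
                 labels = "integer", normalized = "logical"))

setValidity("FeatureMatrix", function(object) {
  msgs <- character()
  v <- object@values
  if (anyNA(v)) msgs <- c(msgs, "feature values must not contain NA")
  if (is.null(colnames(v)) && ncol(v) > 0L)
    msgs <- c(msgs, "feature columns must be named")
  if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
    msgs <- c(msgs, "feature names must be unique")
  if (nrow(object@featureMeta) != ncol(v))
    msgs <- c(msgs, "featureMeta must have one row per feature column")
  if (length(object@labels) != nrow(v))
    msgs <- c(msgs, "labels must have one entry per sample row")
  if (isTRUE(object@normalized) && length(v) > 0L &&
      (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    msgs <- c(msgs, "normalized matrix must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Result of rule-based correlation pruning
#'
#' Records the removed set D and reserved set R produced by processing all
#' high-correlation feature pairs through the five-rule assignment table,
#' plus the ordered list of driving pairs.
#'
#' @slot removed Character vector: feature names in D.
#' @slot reserved Character vector: feature names in R.
#' @slot threshold Correlation threshold T in (0, 1].
#' @slot strict Whether the strict post-pass (no reserved pair above T)
#'   was applied.
#' @slot pairs `data.frame` with columns `X`, `Y`, `rho`, `rule` giving the
#'   high-correlation pairs in processing order and the rule each fired
#'   (0 = recorded only, both already assigned; 6 = strict-mode demotion).
#'
#' @seealso [correlationPrune()], [applyPrune()]
#' @export
setClass("PruneResult",
  representation(removed = "character", reserved = "character",
                 threshold = "numeric", strict = "logical",
                 pairs = "data.frame"))

setValidity("PruneResult", function(object) {
  msgs <- character()
  if (length(intersect(object@removed, object@reserved)) > 0L)
    msgs <- c(msgs, "removed and reserved sets must be disjoint")
  if (object@threshold <= 0 || object@threshold > 1)
    msgs <- c(msgs, "threshold must be in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Principal component model truncated by cumulative contribution
#'
#' Stores the column means, principal axes, eigenvalues and the number of
#' retained components k, chosen as the smallest k whose cumulative
#' eigenvalue share reaches the contribution threshold (or fixed by the
#' caller).
#'
#' @slot center Column mean vector used for centering.
#' @slot rotation Axis matrix (features x components), all components kept
#'   for reconstruction; the first `k` columns are the retained axes.
#' @slot eigenvalues Non-increasing vector of component variances.
#' @slot k Number of retained components.
#' @slot threshold Cumulative contribution threshold T' used (NA when `k`
#'   was fixed by the caller).
#' @slot cumContribution Cumulative eigenvalue shares.
#'
#' @seealso [pcaFit()], [pcaTransform()]
#' @export
setClass("PCAModel",
  representation(center = "numeric", rotation = "matrix",
                 eigenvalues = "numeric", k = "integer",
                 threshold = "numeric", cumContribution = "numeric"))

setValidity("PCAModel", function(object) {
  msgs <- character()
  ev <- object@eigenvalues
  if (length(ev) && any(diff(ev) > 1e-8))
    msgs <- c(msgs, "eigenvalues must be non-increasing")
  if (length(ev) && any(ev < -1e-8))
    msgs <- c(msgs, "eigenvalues must be non-negative")
  if (object@k < 1L || object@k > ncol(object@rotation))
    msgs <- c(msgs, "k must be between 1 and the number of components")
  if (length(msgs)) msgs else TRUE
})

#' Cross-validation evaluation report
#'
#' Confusion counts per fold and pooled, sensitivity/specificity/accuracy
#' as percentages (pooled and per-fold mean +/- sd), and the pooled ROC
#' curve with its trapezoidal area.
#'
#' @slot model Model name (`"svm"`, `"random_forest"`, `"decision_tree"`,
#'   `"naive_bayes"`).
#' @slot foldCounts `data.frame` with columns `fold`, `TP`, `FN`, `TN`,
#'   `FP`.
#' @slot pooled Named numeric: pooled `TP`, `FN`, `TN`, `FP`.
#' @slot metrics Named numeric: pooled `Sn`, `Sp`, `ACC` (percent).
#' @slot foldMetrics `data.frame` of per-fold Sn/Sp/ACC.
#' @slot roc `data.frame` with columns `fpr`, `tpr` (threshold-descending).
#' @slot auc Trapezoidal area under the ROC curve.
#' @slot folds Number of folds.
#' @slot seed Seed used for fold assignment.
#'
#' @seealso [crossValidate()], [confusionMetrics()], [rocCurve()]
#' @export
setClass("EvalReport",
  representation(model = "character", foldCounts = "data.frame",
                 pooled = "numeric", metrics = "numeric",
                 foldMetrics = "data.frame", roc = "data.frame",
                 auc = "numeric", folds = "integer", seed = "integer"))
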