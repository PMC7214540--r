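#' @include AllClasses.R featureMatrix.R
NULL

.pkgCache <- new.env(parent = emptyenv())

#' Three-group property partitions for the 188D descriptor
#'
#' The eight conventional physicochemical attributes (hydrophobicity,
#' normalized van der Waals volume, polarity, polarizability, charge,
#' secondary-structure propensity, solvent accessibility, surface tension),
#' each splitting the 20 residues into three groups. Shipped as a TSV data
#' file so the partitions can be swapped without code changes.
#'
#' @param path Optional path to an alternative partition TSV with columns
#'   `property`, `group1`, `group2`, `group3`.
#' @return A `data.frame` with one row per property.
#' @export
ctdGroups <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.pkgCache$ctd)) {
      path <- system.file("extdata", "ctd_groups.tsv",
                          package = "ThermoRAAC", mustWork = TRUE)
      .pkgCache$ctd <- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    return(.pkgCache$ctd)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Numeric property scales for the auto-cross covariance features
#'
#' The three classic per-residue scales (Kyte-Doolittle hydrophobicity,
#' Hopp-Woods hydrophilicity, side-chain mass), standardized to zero mean
#' and unit variance over the 20 amino acids. Shipped as a TSV data file.
#'
#' @param path Optional path to an alternative scale TSV (first column
#'   `residue`, remaining columns one numeric scale each).
#' @param standardize Standardize each scale over the 20 residues
#'   (default `TRUE`).
#' @return Numeric matrix, 20 rows (residues) x N scales.
#' @export
accScales <- function(path = NULL, standardize = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "acc_scales.tsv",
                        package = "ThermoRAAC", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  m <- m[AA20, , drop = FALSE]
  if (standardize) m <- scale(m)[, , drop = FALSE]
  m
}

# group id (1/2/3) per residue for one property row
.groupIndex <- function(groupsRow) {
  g <- integer(20)
  names(g) <- AA20
  for (j in 1:3) {
    members <- strsplit(groupsRow[[paste0("group", j)]], "", fixed = TRUE)[[1L]]
    g[members] <- j
  }
  g
}

# distribution slots for one group's occurrence positions in a sequence of
# length L: relative positions of the 1st, 25%, 50%, 75% and 100%
# occurrence (ceil(p * n)-th occurrence); absent group -> five zeros
.distSlots <- function(pos, L) {
  if (length(pos) == 0L) return(numeric(5))
  n <- length(pos)
  qidx <- pmax(1L, ceiling(c(0.25, 0.5, 0.75, 1) * n))
  c(pos[1L], pos[qidx]) / L
}

#' The 188-dimensional physicochemical descriptor
#'
#' Computes, per sequence, the classic 188D layout:
#' \itemize{
#'   \item 20 amino acid frequencies (order ACDEFGHIKLMNPQRSTVWY);
#'   \item 24 composition features: for each of 8 property partitions, the
#'     fraction of residues in each of its 3 groups;
#'   \item 120 distribution features: for each property and group, the
#'     relative sequence positions (1-based, divided by L) of the first,
#'     25\%, 50\%, 75\% and 100\% occurrences of that group (the p\%
#'     occurrence is the `ceiling(p * n)`-th of the group's n occurrences;
#'     an absent group contributes five zeros);
#'   \item 24 transition features: for each property, the counts of
#'     adjacent residue pairs crossing each unordered group pair
#'     (1-2, 1-3, 2-3), divided by L - 1.
#' }
#' Computed on the original (unreduced) sequence.
#'
#' @param x A [ProteinSet-class].
#' @param groups Property partition table from [ctdGroups()].
#' @return A [FeatureMatrix-class] with exactly 188 columns, family
#'   `"physchem188"`.
#' @examples
#' fm <- physchem188(ProteinSet(c(s = "AAAA"), labels = 1))
#' dim(fm)  # 1 x 188
#' @export
physchem188 <- function(x, groups = ctdGroups()) {
  stopifnot(is(x, "ProteinSet"))
  nprop <- nrow(groups)
  gidx <- lapply(seq_len(nprop), function(i) .groupIndex(groups[i, ]))
  names(gidx) <- groups$property

  nm <- c(paste("PC|aac", AA20, sep = "|"),
          unlist(lapply(groups$property, function(p)
            paste("PC|comp", p, paste0("g", 1:3), sep = "|"))),
          unlist(lapply(groups$property, function(p)
            unlist(lapply(1:3, function(g)
              paste("PC|dist", p, paste0("g", g),
                    c("first", "p25", "p50", "p75", "p100"), sep = "|"))))),
          unlist(lapply(groups$property, function(p)
            paste("PC|tr", p, c("g1g2", "g1g3", "g2g3"), sep = "|"))))

  seqs <- as.character(x@sequences)
  values <- matrix(0, nrow = length(seqs), ncol = 188L)
  colnames(values) <- nm
  rownames(values) <- names(x@sequences)
  shortWarned <- FALSE

  for (si in seq_along(seqs)) {
    ch <- strsplit(seqs[[si]], "", fixed = TRUE)[[1L]]
    L <- length(ch)
    aac <- tabulate(match(ch, AA20), nbins = 20L) / L
    comp <- numeric(3L * nprop)
    dist <- numeric(15L * nprop)
    tran <- numeric(3L * nprop)
    for (pi in seq_len(nprop)) {
      g <- gidx[[pi]][ch]
      comp[(pi - 1L) * 3L + 1:3] <- tabulate(g, nbins = 3L) / L
      for (gi in 1:3)
        dist[(pi - 1L) * 15L + (gi - 1L) * 5L + 1:5] <-
          .distSlots(which(g == gi), L)
      if (L >= 2L) {
        a <- g[-L]; b <- g[-1L]
        lo <- pmin(a, b); hi <- pmax(a, b)
        tran[(pi - 1L) * 3L + 1:3] <-
          c(sum(lo == 1L & hi == 2L), sum(lo == 1L & hi == 3L),
            sum(lo == 2L & hi == 3L)) / (L - 1L)
      } else if (!shortWarned) {
        warning("length-1 sequence: transition block set to zero")
        shortWarned <- TRUE
      }
    }
    values[si, ] <- c(aac, comp, dist, tran)
  }
  .FeatureMatrix(values, family = "physchem188", labels = x@labels)
}

#' Auto-cross covariance features of property traces
#'
#' Maps each sequence onto N numeric property traces (standardized scale
#' value per residue) and computes, for lags g = 1..lg, the
#' autocovariance of each trace and the cross-covariance of each ordered
#' pair of distinct traces:
#' \deqn{AC(i, g) = \frac{1}{L - g} \sum_{j=1}^{L-g}
#'   (S_{i,j} - \bar S_i)(S_{i,j+g} - \bar S_i)}
#' with \eqn{\bar S_i} the per-sequence mean of trace i, and analogously
#' \eqn{CC(i_1, i_2, g)} with the two traces' own means. The feature count
#' is `N * lg + N * (N - 1) * lg` (18 under the defaults N = 3, lg = 2).
#' Column order: all AC terms (scale-major, lag-minor), then all CC terms
#' (ordered-pair-major, lag-minor).
#'
#' @param x A [ProteinSet-class]; every sequence must be longer than `lg`.
#' @param lg Maximum lag (default 2).
#' @param scales Residue-by-scale matrix from [accScales()].
#' @return A [FeatureMatrix-class], family `"acc"`.
#' @examples
#' fm <- accFeatures(ProteinSet(c(s = "ACDKLM"), labels = 1))
#' ncol(featureValues(fm))  # 18
#' @export
accFeatures <- function(x, lg = 2L, scales = accScales()) {
  stopifnot(is(x, "ProteinSet"))
  lg <- as.integer(lg)
  stopifnot(lg >= 1L)
  N <- ncol(scales)
  sn <- colnames(scales)
  nm <- c(unlist(lapply(sn, function(s) paste("ACC|AC", s, 1:lg, sep = "|"))),
          unlist(lapply(sn, function(s1)
            unlist(lapply(setdiff(sn, s1), function(s2)
              paste("ACC|CC", s1, s2, 1:lg, sep = "|"))))))
  seqs <- as.character(x@sequences)
  values <- matrix(0, nrow = length(seqs), ncol = length(nm))
  colnames(values) <- nm
  rownames(values) <- names(x@sequences)

  for (si in seq_along(seqs)) {
    ch <- strsplit(seqs[[si]], "", fixed = TRUE)[[1L]]
    L <- length(ch)
    if (L <= lg)
      stop("record '", names(x@sequences)[si],
           "' (length ", L, ") is too short for lag ", lg)
    traces <- scales[match(ch, AA20), , drop = FALSE]
    dev <- sweep(traces, 2L, colMeans(traces))
    out <- numeric(length(nm))
    p <- 1L
    for (i in seq_len(N)) for (g in seq_len(lg)) {
      out[p] <- sum(dev[seq_len(L - g), i] * dev[seq_len(L - g) + g, i]) /
        (L - g)
      p <- p + 1L
    }
    for (i1 in seq_len(N)) for (i2 in setdiff(seq_len(N), i1))
      for (g in seq_len(lg)) {
        out[p] <- sum(dev[seq_len(L - g), i1] * dev[seq_len(L - g) + g, i2]) /
          (L - g)
        p <- p + 1L
      }
    values[si, ] <- out
  }
  .FeatureMatrix(values, family = "acc", labels = x@labels)
}
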