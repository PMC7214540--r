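#' @include AllClasses.R AllGenerics.R
NULL

# Internal constructor; meta columns recycled over features.
.FeatureMatrix <- function(values, family, lambda = NA_integer_,
                           labels = NA_integer_, normalized = FALSE) {
  if (length(labels) == 1L) labels <- rep(as.integer(labels), nrow(values))
  meta <- DataFrame(name = colnames(values),
                    family = rep(family, length.out = ncol(values)),
                    lambda = rep(as.integer(lambda),
                                 length.out = ncol(values)))
  new("FeatureMatrix", values = values, featureMeta = meta,
      labels = as.integer(labels), normalized = normalized)
}

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname featureMeta
#' @export
setMethod("featureMeta", "FeatureMatrix", function(x) x@featureMeta)

#' @rdname isNormalized
#' @export
setMethod("isNormalized", "FeatureMatrix", function(x) x@normalized)

#' Row labels of a FeatureMatrix
#' @param object A [FeatureMatrix-class].
#' @param ... Unused.
#' @return Integer 0/1/`NA` label per sample row.
#' @export
setMethod("labels", "FeatureMatrix", function(object, ...) object@labels)

#' @describeIn FeatureMatrix Dimensions (samples, features).
#' @param x A `FeatureMatrix`.
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

setMethod("show", "FeatureMatrix", function(object) {
  fam <- table(object@featureMeta$family)
  cat(sprintf("FeatureMatrix: %d samples x %d features%s\n",
              nrow(object@values), ncol(object@values),
              if (object@normalized) " (normalized)" else ""))
  cat("  families:", paste(sprintf("%s(%d)", names(fam), fam),
                           collapse = ", "), "\n")
})

#' @describeIn FeatureMatrix Subset samples (i) and/or features (j, by
#'   index or name).
#' @param i,j Row (sample) / column (feature) indices.
#' @param ... Unused.
#' @param drop Ignored (always `FALSE`).
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  if (is.character(j)) j <- match(j, colnames(x@values))
  new("FeatureMatrix", values = x@values[i, j, drop = FALSE],
      featureMeta = x@featureMeta[j, , drop = FALSE],
      labels = x@labels[i], normalized = x@normalized)
})

#' Column-bind feature families computed on the same samples
#'
#' @param ... `FeatureMatrix` objects with identical row counts and labels.
#' @return A combined [FeatureMatrix-class].
#' @export
cbindFeatures <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  labs <- parts[[1L]]@labels
  for (p in parts[-1L])
    if (!identical(p@labels, labs))
      stop("feature matrices disagree on sample labels")
  values <- do.call(cbind, lapply(parts, featureValues))
  meta <- do.call(rbind, lapply(parts, featureMeta))
  new("FeatureMatrix", values = values, featureMeta = meta, labels = labs,
      normalized = all(vapply(parts, isNormalized, logical(1))))
}

#' Write / read a FeatureMatrix as CSV
#'
#' The CSV has a header row of feature names; the first two columns are
#' `id` and `label`.
#'
#' @param x A [FeatureMatrix-class].
#' @param path Output CSV path.
#' @return `path` invisibly (`writeFeatureCSV`); a [FeatureMatrix-class]
#'   (`readFeatureCSV`, feature families recovered from the name prefixes).
#' @export
writeFeatureCSV <- function(x, path) {
  df <- data.frame(id = rownames(x@values), label = x@labels,
                   x@values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df$id
  fam <- .familyFromName(colnames(values))
  lam <- ifelse(fam == "dipeptide",
                suppressWarnings(as.integer(
                  vapply(strsplit(colnames(values), "|", fixed = TRUE),
                         function(p) if (length(p) >= 2L) p[[2L]]
                         else NA_character_, character(1)))),
                NA_integer_)
  meta <- DataFrame(name = colnames(values), family = fam, lambda = lam)
  new("FeatureMatrix", values = values, featureMeta = meta,
      labels = as.integer(df$label),
      normalized = min(values) >= 0 && max(values) <= 1)
}

.familyFromName <- function(nm) {
  ifelse(startsWith(nm, "RD|"), "dipeptide",
         ifelse(startsWith(nm, "ACC|"), "acc",
                ifelse(startsWith(nm, "PC|"), "physchem188", "pca")))
}

#' Assemble the mixed feature set for a dataset
#'
#' Computes and column-binds the requested feature families: the
#' 188-dimensional physicochemical descriptor and the auto-cross
#' covariance features on the original sequences, and the gapped dipeptide
#' frequencies on the scheme-reduced sequences. With
#' `originalDipeptides = TRUE` the dipeptide family is computed over the
#' unreduced 20-letter alphabet instead (ablation arm).
#'
#' @param x A [ProteinSet-class].
#' @param families Character subset of
#'   `c("physchem188", "dipeptide", "acc")`.
#' @param scheme [ReductionScheme-class] for the dipeptide family.
#' @param maxGap Largest dipeptide gap lambda (default 2).
#' @param lg Maximum auto-cross covariance lag (default 2).
#' @param originalDipeptides Use the identity alphabet for dipeptides.
#' @return A [FeatureMatrix-class] (1289 columns under the defaults:
#'   188 + 3 x 361 + 18).
#' @export
extractFeatures <- function(x,
                            families = c("physchem188", "dipeptide", "acc"),
                            scheme = builtinScheme("susko19"),
                            maxGap = 2L, lg = 2L,
                            originalDipeptides = FALSE) {
  families <- match.arg(families, several.ok = TRUE)
  parts <- list()
  if ("physchem188" %in% families)
    parts <- c(parts, list(physchem188(x)))
  if ("dipeptide" %in% families) {
    dip <- if (originalDipeptides)
      originalDipeptideFeatures(x, maxGap = maxGap)
    else gappedDipeptideFeatures(x, scheme = scheme, maxGap = maxGap)
    parts <- c(parts, list(dip))
  }
  if ("acc" %in% families)
    parts <- c(parts, list(accFeatures(x, lg = lg)))
  do.call(cbindFeatures, parts)
}
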