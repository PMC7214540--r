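#' @include AllClasses.R
NULL

#' Extract the amino acid sequences of a dataset
#'
#' @param x A [ProteinSet-class].
#' @param ... Further arguments (unused).
#' @return An [Biostrings::AAStringSet-class].
#' @export
setGeneric("sequences", function(x, ...) standardGeneric("sequences"))

#' Number of positive (thermophilic) records
#' @param x A [ProteinSet-class].
#' @return Integer count of records labelled positive.
#' @export
setGeneric("nPositive", function(x) standardGeneric("nPositive"))

#' Number of negative (non-thermophilic) records
#' @param x A [ProteinSet-class].
#' @return Integer count of records labelled negative.
#' @export
setGeneric("nNegative", function(x) standardGeneric("nNegative"))

#' Feature value matrix of a FeatureMatrix
#' @param x A [FeatureMatrix-class].
#' @return Numeric matrix, samples in rows, features in columns.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Per-column feature metadata
#' @param x A [FeatureMatrix-class].
#' @return A [S4Vectors::DataFrame-class] with columns `name`, `family`,
#'   `lambda`.
#' @export
setGeneric("featureMeta", function(x) standardGeneric("featureMeta"))

#' Has a FeatureMatrix been min-max normalized?
#' @param x A [FeatureMatrix-class].
#' @return Logical scalar.
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' Names of removed (pruned) features
#' @param x A [PruneResult-class].
#' @return Character vector of feature names in the removed set D.
#' @export
setGeneric("removedFeatures", function(x) standardGeneric("removedFeatures"))

#' Names of reserved features
#' @param x A [PruneResult-class].
#' @return Character vector of feature names in the reserved set R.
#' @export
setGeneric("reservedFeatures", function(x) standardGeneric("reservedFeatures"))
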