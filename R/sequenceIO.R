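#' @include AllClasses.R AllGenerics.R
NULL

# Evaluate expr with a locally seeded RNG, restoring global RNG state after.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Construct a ProteinSet
#'
#' @param sequences Named character vector or `AAStringSet` of protein
#'   sequences over the 20 standard residues (uppercased on construction).
#' @param labels Binary class labels (1 = thermophilic), recycled `NA` when
#'   omitted.
#' @return A [ProteinSet-class].
#' @examples
#' ps <- ProteinSet(c(p1 = "ACDE", p2 = "KKRE"), labels = c(1, 0))
#' nPositive(ps)
#' @export
ProteinSet <- function(sequences, labels = NA) {
  if (is.character(sequences)) {
    sequences <- toupper(sequences)
    sequences <- Biostrings::AAStringSet(sequences)
  }
  labels <- as.integer(labels)
  if (length(labels) == 1L)
    labels <- rep(labels, length(sequences))
  new("ProteinSet", sequences = sequences, labels = labels)
}

#' @describeIn ProteinSet Number of records.
#' @param x A `ProteinSet`.
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' @rdname sequences
#' @export
setMethod("sequences", "ProteinSet", function(x, ...) x@sequences)

#' Class labels of a ProteinSet
#'
#' @param object A [ProteinSet-class].
#' @param ... Unused.
#' @return Integer vector of 0/1/`NA` labels (1 = thermophilic).
#' @export
setMethod("labels", "ProteinSet", function(object, ...) object@labels)

#' @rdname nPositive
#' @export
setMethod("nPositive", "ProteinSet",
  function(x) sum(x@labels == 1L, na.rm = TRUE))

#' @rdname nNegative
#' @export
setMethod("nNegative", "ProteinSet",
  function(x) sum(x@labels == 0L, na.rm = TRUE))

#' @describeIn ProteinSet Subset records by index, id or logical mask.
#' @param i Index vector.
#' @param j,drop Ignored.
#' @param ... Unused.
#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("ProteinSet", sequences = x@sequences[i], labels = x@labels[i])
})

setMethod("show", "ProteinSet", function(object) {
  cat(sprintf(
    "ProteinSet with %d records (%d positive, %d negative, %d unlabelled)\n",
    length(object), nPositive(object), nNegative(object),
    sum(is.na(object@labels))))
  if (length(object) > 0L) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("  sequence length: %d-%d (median %d)\n",
                min(w), max(w), as.integer(stats::median(w))))
  }
})

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a [ProteinSet-class]. Sequences are uppercased;
#' multi-line bodies are concatenated. Residues outside the 20-letter
#' alphabet are rejected under the default `"strict"` policy; under
#' `"drop-record"` the offending records are dropped with a warning. The
#' characters `*` and `-` are rejected under every policy, since no
#' descriptor is defined over them.
#'
#' @param path Path to a FASTA file.
#' @param label Optional binary label (1 = thermophilic) applied to all
#'   records in the file.
#' @param policy `"strict"` (error on non-standard residues) or
#'   `"drop-record"`.
#' @return A [ProteinSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "acd", "EFG"), fa)
#' readFastaProteins(fa, label = 1)
#' @export
readFastaProteins <- function(path, label = NA,
                              policy = c("strict", "drop-record")) {
  policy <- match.arg(policy)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop("no records in FASTA file '", path, "'")
  seqs <- toupper(as.character(raw))
  # FASTA headers may carry descriptions; the id is the first word
  ids <- vapply(strsplit(names(raw), "[ \t]"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate record id '", ids[anyDuplicated(ids)], "' in '", path, "'")
  names(seqs) <- ids

  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    ch <- unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1L]])
    off <- setdiff(ch, AA20)
    if (length(off) == 0L) next
    if (any(off %in% c("*", "-")))
      stop("record '", ids[i], "' contains forbidden character '",
           intersect(off, c("*", "-"))[1L], "'")
    if (policy == "strict")
      stop("record '", ids[i], "' contains non-standard residue '",
           off[1L], "'")
    warning("dropping record '", ids[i], "' with non-standard residue '",
            off[1L], "'")
    keep[i] <- FALSE
  }
  seqs <- seqs[keep]
  if (length(seqs) == 0L)
    stop("no records left after dropping non-standard sequences")
  ProteinSet(seqs, labels = label)
}

#' Write a ProteinSet to FASTA (and optionally a label TSV)
#'
#' @param x A [ProteinSet-class].
#' @param path Output FASTA path.
#' @param labelPath Optional path for a two-column `id<TAB>label` TSV of
#'   the labelled records.
#' @return `path`, invisibly.
#' @export
writeFastaProteins <- function(x, path, labelPath = NULL) {
  Biostrings::writeXStringSet(x@sequences, filepath = path)
  if (!is.null(labelPath)) {
    lab <- x@labels
    df <- data.frame(id = names(x@sequences)[!is.na(lab)],
                     label = lab[!is.na(lab)])
    utils::write.table(df, labelPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a two-column label file and attach labels to a ProteinSet
#'
#' The file is tab-separated, `id<TAB>label` with label 0 or 1; one header
#' line is allowed and detected automatically.
#'
#' @param x A [ProteinSet-class].
#' @param path Path to the label TSV.
#' @return `x` with labels filled in.
#' @export
attachLabels <- function(x, path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2L)
    stop("label file must have two tab-separated columns")
  if (!tab[1L, 2L] %in% c("0", "1"))
    tab <- tab[-1L, , drop = FALSE]
  if (!all(tab[[2L]] %in% c("0", "1")))
    stop("labels must be 0 or 1")
  idx <- match(tab[[1L]], names(x@sequences))
  if (anyNA(idx))
    stop("label file refers to unknown id '", tab[[1L]][which(is.na(idx))[1L]],
         "'")
  lab <- x@labels
  lab[idx] <- as.integer(tab[[2L]])
  initialize(x, labels = lab)
}

#' Balanced subsampling of a labelled dataset
#'
#' Draws exactly `nPerClass` records from each class without replacement,
#' deterministically for a fixed seed, preserving the relative input order
#' of the selected records. This mirrors the common experimental convention
#' of balancing an unbalanced two-class sequence collection (e.g. drawing
#' 500 of each class) before cross-validation.
#'
#' @param x A labelled [ProteinSet-class].
#' @param nPerClass Number of records to keep per class.
#' @param seed Integer seed controlling the draw.
#' @return A [ProteinSet-class] with `2 * nPerClass` records.
#' @examples
#' ps <- ProteinSet(setNames(rep("ACDK", 10), paste0("s", 1:10)),
#'                  labels = rep(c(0, 1), 5))
#' length(sampleBalanced(ps, 3, seed = 1))
#' @export
sampleBalanced <- function(x, nPerClass, seed) {
  pos <- which(x@labels == 1L)
  neg <- which(x@labels == 0L)
  if (length(pos) < nPerClass)
    stop("positive class has only ", length(pos), " records; need ",
         nPerClass)
  if (length(neg) < nPerClass)
    stop("negative class has only ", length(neg), " records; need ",
         nPerClass)
  sel <- .withSeed(seed, {
    c(sample(pos, nPerClass), sample(neg, nPerClass))
  })
  x[sort(sel)]
}
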