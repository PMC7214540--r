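#' @include AllClasses.R
NULL

#' Built-in reduced amino acid alphabet schemes
#'
#' Returns one of the registered reduction schemes:
#' \describe{
#'   \item{`susko19`}{19 classes; Ile and Val form one class with
#'     representative V, every other residue is its own class. This is the
#'     final scheme of the Susko substitution-bin family.}
#'   \item{`dayhoff6`}{the six Dayhoff classes AGPST | DENQ | HKR | ILMV |
#'     FWY | C; each representative is the group's first letter.}
#'   \item{`identity20`}{the identity map over the 20 residues, used for
#'     the original-dipeptide ablation.}
#' }
#'
#' @param name One of `"susko19"`, `"dayhoff6"`, `"identity20"`.
#' @return A [ReductionScheme-class].
#' @examples
#' builtinScheme("susko19")
#' @export
builtinScheme <- function(name) {
  schemes <- list(
    susko19 = list(
      groups = c("A", "C", "D", "E", "F", "G", "H", "IV", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "W", "Y"),
      representatives = c("A", "C", "D", "E", "F", "G", "H", "V", "K", "L",
                          "M", "N", "P", "Q", "R", "S", "T", "W", "Y")),
    dayhoff6 = list(
      groups = c("AGPST", "DENQ", "HKR", "ILMV", "FWY", "C"),
      representatives = c("A", "D", "H", "I", "F", "C")),
    identity20 = list(
      groups = AA20,
      representatives = AA20))
  if (!name %in% names(schemes))
    stop("unknown scheme '", name, "'; available: ",
         paste(names(schemes), collapse = ", "))
  s <- schemes[[name]]
  new("ReductionScheme", name = name, groups = s$groups,
      representatives = s$representatives)
}

#' Load a custom reduction scheme from a plain-text file
#'
#' One group per line, letters concatenated (e.g. `AGPST`). Lines must
#' partition the 20-letter alphabet; the representative of each group is
#' its first letter unless the line is written `rep:members`.
#'
#' @param path Path to the scheme file.
#' @param name Name to record for the scheme (default: the file name).
#' @return A [ReductionScheme-class].
#' @export
readSchemeFile <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- toupper(trimws(lines))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty scheme file")
  parts <- strsplit(lines, ":", fixed = TRUE)
  groups <- vapply(parts, function(p) p[[length(p)]], character(1))
  reps <- vapply(parts, function(p)
    if (length(p) == 2L) p[[1L]] else substr(p[[1L]], 1L, 1L), character(1))
  new("ReductionScheme", name = name, groups = groups,
      representatives = reps)
}

#' @describeIn ReductionScheme Number of classes k.
#' @param x A `ReductionScheme`.
#' @export
setMethod("length", "ReductionScheme", function(x) length(x@groups))

setMethod("show", "ReductionScheme", function(object) {
  cat(sprintf("ReductionScheme '%s' with %d classes\n", object@name,
              length(object@groups)))
  cat("  ", paste(ifelse(nchar(object@groups) > 1L,
                         paste0(object@groups, "->", object@representatives),
                         object@groups), collapse = " "), "\n", sep = "")
})

# residue -> representative lookup vector for a scheme
.schemeMap <- function(scheme) {
  members <- strsplit(scheme@groups, "", fixed = TRUE)
  map <- rep(scheme@representatives, lengths(members))
  names(map) <- unlist(members)
  map[AA20]
}

#' Recode sequences onto a reduced alphabet
#'
#' Replaces every residue by the representative symbol of its class. The
#' output has the same length as the input; composition over classes is
#' conserved.
#'
#' @param x A character vector of validated protein sequences, or a
#'   [ProteinSet-class].
#' @param scheme A [ReductionScheme-class].
#' @return Character vector of recoded sequences (named like the input).
#' @examples
#' reduceSequence("IVIV", builtinScheme("susko19"))  # "VVVV"
#' @export
reduceSequence <- function(x, scheme) {
  if (is(x, "ProteinSet")) {
    seqs <- as.character(x@sequences)
  } else {
    seqs <- x
  }
  map <- .schemeMap(scheme)
  out <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    rep_ch <- map[ch]
    if (anyNA(rep_ch))
      stop("residue '", ch[which(is.na(rep_ch))[1L]],
           "' not covered by scheme '", scheme@name, "'")
    paste(rep_ch, collapse = "")
  }, character(1))
  names(out) <- names(seqs)
  out
}
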