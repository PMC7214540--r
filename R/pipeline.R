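#' @include AllClasses.R featureMatrix.R reduce.R mrmd.R pca.R evaluate.R
NULL

#' Run the full recognition pipeline
#'
#' End-to-end orchestration in the canonical stage order: optional
#' balanced subsampling, mixed feature extraction (188D physicochemical +
#' reduced gapped dipeptides + auto-cross covariance), min-max
#' normalization, rule-based correlation pruning, MRMD ranking with
#' accuracy-driven truncation, PCA truncated by cumulative contribution,
#' and stratified k-fold cross-validation of the requested classifiers.
#' One master seed is expanded into independent per-stage seeds
#' (subsampling, MRMD internal folds, final fold assignment) so the whole
#' run replays bit-identically.
#'
#' @param x A labelled [ProteinSet-class].
#' @param outDir Optional directory; when given, the assembled feature
#'   matrix, prune report, MRMD trace, per-model evaluation JSON and a
#'   machine-readable manifest of all effective parameters are written
#'   there.
#' @param scheme Reduction scheme name or [ReductionScheme-class]
#'   (default `"susko19"`).
#' @param maxGap Largest dipeptide gap (default 2).
#' @param families Feature families to extract.
#' @param originalDipeptides Ablation: dipeptides over the unreduced
#'   alphabet.
#' @param threshold Correlation pruning threshold T (default 0.85).
#' @param strictPrune Strict prune mode (see [correlationPrune()]).
#' @param mrmdMode,patience,mrmdFolds MRMD truncation controls (see
#'   [mrmdSelect()]).
#' @param pcaThreshold Cumulative contribution threshold T' (default
#'   0.95).
#' @param pcaK Fixed component count overriding `pcaThreshold`.
#' @param models Character vector of classifiers to evaluate.
#' @param folds Cross-validation folds (default 10).
#' @param nPerClass Balanced subsample size per class (`NULL` = use all
#'   records; the classic external-dataset convention is 500).
#' @param seed Master seed.
#' @return A list with elements `data`, `features` (normalized
#'   [FeatureMatrix-class]), `prune`, `ranking`, `selection`, `pca`,
#'   `components`, `reports` (named list of [EvalReport-class]), and
#'   `params`.
#' @examples
#' \donttest{
#' ps <- generateProteins(generatorSpec(40, 40, c(60, 120), delta = 0.06,
#'                                      seed = 3))
#' run <- runPipeline(ps, folds = 4, models = "svm", seed = 3)
#' run$reports$svm
#' }
#' @export
runPipeline <- function(x, outDir = NULL,
                        scheme = "susko19", maxGap = 2L,
                        families = c("physchem188", "dipeptide", "acc"),
                        originalDipeptides = FALSE,
                        threshold = 0.85, strictPrune = FALSE,
                        mrmdMode = "grid", patience = Inf,
                        mrmdFolds = 5L,
                        pcaThreshold = 0.95, pcaK = NULL,
                        models = "svm", folds = 10L,
                        nPerClass = NULL, seed = 1L) {
  stopifnot(is(x, "ProteinSet"), length(families) >= 1L, folds >= 2L,
            threshold > 0, threshold <= 1)
  if (is.character(scheme)) scheme <- builtinScheme(scheme)
  stageSeeds <- .withSeed(seed, sample.int(2147483L, 4L))

  if (!is.null(nPerClass))
    x <- sampleBalanced(x, nPerClass, seed = stageSeeds[1L])
  message("pipeline: ", length(x), " records (", nPositive(x), " pos / ",
          nNegative(x), " neg)")

  fm <- extractFeatures(x, families = families, scheme = scheme,
                        maxGap = maxGap,
                        originalDipeptides = originalDipeptides)
  message("extract: ", ncol(featureValues(fm)), " features")

  nfm <- suppressWarnings(normalizeFeatures(fm))
  prune <- correlationPrune(nfm, threshold = threshold,
                            strict = strictPrune)
  pruned <- applyPrune(nfm, prune)
  message("prune (T = ", threshold, "): ", length(prune@removed),
          " removed, ", ncol(featureValues(pruned)), " kept")

  ranking <- mrmdRank(pruned)
  selection <- mrmdSelect(pruned, ranking = ranking, folds = mrmdFolds,
                          seed = stageSeeds[2L], mode = mrmdMode,
                          patience = patience)
  selected <- pruned[, selection$features]
  message("mrmd: k = ", selection$k, " features selected")

  pca <- pcaFit(selected, threshold = pcaThreshold, kOverride = pcaK)
  comps <- pcaTransform(pca, selected)
  message("pca: ", pca@k, " components")

  reports <- lapply(models, function(m)
    crossValidate(comps, model = m, folds = folds,
                  seed = stageSeeds[3L]))
  names(reports) <- models
  for (m in models)
    message(sprintf("eval [%s]: ACC = %.2f%%  AUC = %.3f", m,
                    reports[[m]]@metrics["ACC"], reports[[m]]@auc))

  params <- list(scheme = scheme@name, maxGap = maxGap,
                 families = families,
                 originalDipeptides = originalDipeptides,
                 threshold = threshold, strictPrune = strictPrune,
                 mrmdMode = mrmdMode, patience = patience,
                 mrmdFolds = mrmdFolds, pcaThreshold = pcaThreshold,
                 pcaK = pcaK, models = models, folds = folds,
                 nPerClass = nPerClass, seed = seed,
                 stageSeeds = stageSeeds)
  run <- list(data = x, features = nfm, prune = prune, ranking = ranking,
              selection = selection, pca = pca, components = comps,
              reports = reports, params = params)
  if (!is.null(outDir)) .writeRunDir(run, outDir)
  run
}

.writeRunDir <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeFeatureCSV(run$features, file.path(outDir, "features.csv"))
  writePruneCSV(run$prune, file.path(outDir, "prune.csv"))
  utils::write.csv(as.data.frame(run$ranking),
                   file.path(outDir, "mrmd_ranking.csv"), row.names = FALSE)
  utils::write.csv(run$selection$trace,
                   file.path(outDir, "mrmd_trace.csv"), row.names = FALSE)
  pca <- run$pca
  utils::write.csv(data.frame(component = seq_along(pca@eigenvalues),
                              eigenvalue = pca@eigenvalues,
                              cumulative = pca@cumContribution),
                   file.path(outDir, "pca_eigenvalues.csv"),
                   row.names = FALSE)
  for (m in names(run$reports))
    writeEvalJSON(run$reports[[m]],
                  file.path(outDir, paste0("eval_", m, ".json")))
  jsonlite::write_json(run$params, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outDir)
}

#' Ranked / removed feature report
#'
#' Emits the top-n retained features by MRMD total, and the removed
#' dipeptide features collapsed over the gap index (the "omit the gap
#' symbols" view): a residue pair removed at several gaps appears once
#' with its multiplicity, and only pairs reaching `minMultiplicity`
#' (default 2) are listed.
#'
#' @param prune A [PruneResult-class].
#' @param ranking An MRMD ranking ([mrmdRank()]) of the retained features.
#' @param topN Number of top features to report (default 10).
#' @param minMultiplicity Collapsed-pair inclusion threshold.
#' @return List with `top` (DataFrame), `removedByFamily` (table) and
#'   `collapsedPairs` (`data.frame(pair, multiplicity)`).
#' @export
reportFeatures <- function(prune, ranking, topN = 10L,
                           minMultiplicity = 2L) {
  if (topN > nrow(ranking)) {
    warning("only ", nrow(ranking), " retained features; truncating")
    topN <- nrow(ranking)
  }
  top <- ranking[seq_len(topN), ]
  fam <- table(.familyFromName(prune@removed))
  dips <- prune@removed[startsWith(prune@removed, "RD|")]
  collapsed <- data.frame(pair = character(), multiplicity = integer())
  if (length(dips) > 0L) {
    parts <- strsplit(dips, "|", fixed = TRUE)
    pair <- vapply(parts, function(p) paste0(p[[3L]], p[[4L]]), character(1))
    tab <- table(pair)
    tab <- tab[tab >= minMultiplicity]
    collapsed <- data.frame(pair = names(tab),
                            multiplicity = as.integer(tab))
  }
  list(top = top, removedByFamily = fam, collapsedPairs = collapsed)
}
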