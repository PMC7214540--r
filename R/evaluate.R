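#' @include AllClasses.R featureMatrix.R sequenceIO.R
NULL

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `Sn = TP / (TP + FN) * 100` (thermophilic recall),
#' `Sp = TN / (TN + FP) * 100`, `ACC = (TP + TN) / total * 100`. A class
#' with no observations yields `NA` for its recall rather than 0.
#'
#' @param TP,FN,TN,FP Non-negative confusion counts.
#' @return Named numeric vector `c(Sn, Sp, ACC)` in percent.
#' @examples
#' confusionMetrics(TP = 9, FN = 1, TN = 8, FP = 2)  # 90 80 85
#' @export
confusionMetrics <- function(TP, FN, TN, FP) {
  total <- TP + FN + TN + FP
  if (total == 0) stop("all confusion counts are zero")
  Sn <- if (TP + FN == 0) NA_real_ else TP / (TP + FN) * 100
  Sp <- if (TN + FP == 0) NA_real_ else TN / (TN + FP) * 100
  c(Sn = Sn, Sp = Sp, ACC = (TP + TN) / total * 100)
}

#' ROC curve and trapezoidal area
#'
#' Thresholds descend through the unique score values; tied scores form a
#' single threshold step. The curve starts at (0, 0) and ends at (1, 1).
#'
#' @param scores Real-valued classifier scores (larger = more positive).
#' @param labels Binary labels (1 = positive).
#' @return List with `points` (`data.frame(fpr, tpr)`) and `auc`.
#' @examples
#' rocCurve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc  # 1
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l == 1L); fp <- cumsum(l == 0L)
  # keep only the last index of each tie group (one step per threshold)
  keep <- c(diff(s) != 0, TRUE)
  tpr <- c(0, tp[keep] / P)
  fpr <- c(0, fp[keep] / N)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# fit one classifier and return list(predict_class, predict_score)
.fitModel <- function(model, train, ytrain) {
  yf <- factor(ytrain, levels = c(0L, 1L))
  switch(model,
    svm = {
      fit <- e1071::svm(x = train, y = yf, kernel = "radial", cost = 1,
                        scale = FALSE)
      list(
        cls = function(test) as.integer(as.character(predict(fit, test))),
        score = function(test) {
          dv <- attr(predict(fit, test, decision.values = TRUE),
                     "decision.values")
          # orient decision values so larger = more positive-class
          if (strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L] == "1")
            dv[, 1L] else -dv[, 1L]
        })
    },
    random_forest = {
      fit <- randomForest::randomForest(x = train, y = yf, ntree = 100L)
      list(
        cls = function(test) as.integer(as.character(predict(fit, test))),
        score = function(test)
          predict(fit, test, type = "prob")[, "1"])
    },
    decision_tree = {
      df <- data.frame(.y = yf, train, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      list(
        cls = function(test) {
          p <- predict(fit, data.frame(test, check.names = FALSE),
                       type = "class")
          as.integer(as.character(p))
        },
        score = function(test)
          predict(fit, data.frame(test, check.names = FALSE),
                  type = "prob")[, "1"])
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x = as.data.frame(train), y = yf)
      list(
        cls = function(test) {
          p <- predict(fit, as.data.frame(test))
          as.integer(as.character(p))
        },
        score = function(test)
          predict(fit, as.data.frame(test), type = "raw")[, "1"])
    },
    stop("unknown model '", model, "'; available: svm, random_forest, ",
         "decision_tree, naive_bayes"))
}

# deterministic stratified fold assignment
.stratifiedFolds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  .withSeed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      assign[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  assign
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Assigns observations to stratified folds deterministically for a given
#' seed, trains the requested model on each training split and predicts
#' the held-out fold; reports per-fold and pooled confusion counts,
#' Sn/Sp/ACC, and the pooled ROC curve built from the model's continuous
#' scores on held-out observations.
#'
#' @param x A labelled [FeatureMatrix-class], or a numeric matrix with
#'   `labels` supplied.
#' @param model One of `"svm"` (RBF kernel, C = 1, default gamma),
#'   `"random_forest"` (100 trees), `"decision_tree"`, `"naive_bayes"`.
#' @param folds Number of folds (default 10); every class must have at
#'   least `folds` members.
#' @param seed Integer seed for fold assignment and any stochastic fit.
#' @param labels Binary labels when `x` is a plain matrix.
#' @return An [EvalReport-class].
#' @export
crossValidate <- function(x, model = "svm", folds = 10L, seed = 1L,
                          labels = NULL) {
  if (is(x, "FeatureMatrix")) {
    v <- x@values; labs <- x@labels
  } else {
    v <- as.matrix(x); labs <- as.integer(labels)
  }
  folds <- as.integer(folds)
  if (folds < 2L) stop("need at least 2 folds")
  if (anyNA(labs)) stop("cross-validation needs labels on every sample")
  for (cl in c(0L, 1L))
    if (sum(labs == cl) < folds)
      stop("class ", cl, " has ", sum(labs == cl),
           " observations, fewer than ", folds, " folds")
  assign <- .stratifiedFolds(labs, folds, seed)

  scores <- numeric(length(labs))
  predcls <- integer(length(labs))
  foldCounts <- data.frame(fold = seq_len(folds), TP = 0L, FN = 0L,
                           TN = 0L, FP = 0L)
  for (f in seq_len(folds)) {
    te <- assign == f
    fitted <- .withSeed(seed * 1000L + f,
                        .fitModel(model, v[!te, , drop = FALSE], labs[!te]))
    predcls[te] <- fitted$cls(v[te, , drop = FALSE])
    scores[te] <- fitted$score(v[te, , drop = FALSE])
    foldCounts$TP[f] <- sum(predcls[te] == 1L & labs[te] == 1L)
    foldCounts$FN[f] <- sum(predcls[te] == 0L & labs[te] == 1L)
    foldCounts$TN[f] <- sum(predcls[te] == 0L & labs[te] == 0L)
    foldCounts$FP[f] <- sum(predcls[te] == 1L & labs[te] == 0L)
  }
  pooled <- c(TP = sum(foldCounts$TP), FN = sum(foldCounts$FN),
              TN = sum(foldCounts$TN), FP = sum(foldCounts$FP))
  foldMetrics <- do.call(rbind, lapply(seq_len(folds), function(f)
    data.frame(fold = f, t(confusionMetrics(
      foldCounts$TP[f], foldCounts$FN[f], foldCounts$TN[f],
      foldCounts$FP[f])))))
  roc <- rocCurve(scores, labs)
  new("EvalReport", model = model, foldCounts = foldCounts,
      pooled = pooled,
      metrics = confusionMetrics(unname(pooled["TP"]), unname(pooled["FN"]),
                                 unname(pooled["TN"]), unname(pooled["FP"])),
      foldMetrics = foldMetrics, roc = roc$points, auc = roc$auc,
      folds = folds, seed = as.integer(seed))
}

setMethod("show", "EvalReport", function(object) {
  m <- object@metrics
  fm <- object@foldMetrics
  cat(sprintf("EvalReport [%s], %d-fold CV (seed %d)\n", object@model,
              object@folds, object@seed))
  cat(sprintf("  pooled: Sn = %.2f%%  Sp = %.2f%%  ACC = %.2f%%  AUC = %.3f\n",
              m["Sn"], m["Sp"], m["ACC"], object@auc))
  cat(sprintf("  per-fold ACC: %.2f +/- %.2f%%\n",
              mean(fm$ACC), stats::sd(fm$ACC)))
})

#' Serialize an EvalReport to JSON
#'
#' Writes counts (per fold and pooled), metrics and ROC points.
#'
#' @param report An [EvalReport-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeEvalJSON <- function(report, path) {
  jsonlite::write_json(list(
    model = report@model, folds = report@folds, seed = report@seed,
    pooled = as.list(report@pooled),
    metrics = as.list(report@metrics),
    fold_metrics = report@foldMetrics,
    auc = report@auc, roc = report@roc), path, auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}
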