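# Evaluation protocol: stratified 5-fold cross-validation, confusion-matrix
# metrics, ROC/AUC, reader precision, and localization hit scoring.

#' Stratified k-fold split
#'
#' Cases are shuffled by seed within each class, the class groups are
#' concatenated, and cases are dealt round-robin to folds K1..Kk with a
#' running fold pointer, so fold sizes differ by at most one overall and per
#' class.
#'
#' @param labels 0/1 class labels.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @param ids optional case identifiers (defaults to indices).
#' @param stratified deal per class (default) or ignore labels.
#' @return a `FoldSplit` list: `folds` (list of k id vectors), `k`, `seed`,
#'   `stratified`.
#' @export
makeFolds <- function(labels, k = 5L, seed = 1L, ids = seq_along(labels),
                      stratified = TRUE) {
  n <- length(labels)
  if (n < k) stop("need at least k = ", k, " cases, got ", n)
  ord <- withSeed(seed, {
    if (stratified) {
      unlist(lapply(sort(unique(labels)), function(cl) {
        idx <- which(labels == cl)
        idx[sample.int(length(idx))]
      }), use.names = FALSE)
    } else sample.int(n)
  })
  assign <- rep_len(seq_len(k), n)
  folds <- split(ids[ord], assign)
  names(folds) <- paste0("K", seq_len(k))
  structure(list(folds = folds, k = as.integer(k), seed = as.integer(seed),
                 stratified = stratified), class = "FoldSplit")
}

#' @export
print.FoldSplit <- function(x, ...) {
  cat(sprintf("FoldSplit: k = %d, seed = %d, %s; sizes %s\n", x$k, x$seed,
              if (x$stratified) "stratified" else "unstratified",
              paste(lengths(x$folds), collapse = "/")))
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' `acc = (tp+tn)/total`, `pre = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `spe = tn/(tn+fp)`, `f1 = 2*pre*recall/(pre+recall)`. A metric whose
#' denominator is zero is reported as `NA` (undefined, never coerced to 0)
#' and named in the `undefined` field.
#'
#' @param counts a [ConfusionCounts-class].
#' @return list with `acc`, `pre`, `recall`, `spe`, `f1`, and `undefined`
#'   (character vector of metrics with empty denominators).
#' @examples
#' computeMetrics(confusionCounts(tp = 548, tn = 654, fp = 62, fn = 132))
#' @export
computeMetrics <- function(counts) {
  validObject(counts)
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  total <- tp + tn + fp + fn
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- (tp + tn) / total
  pre <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  spe <- rat(tn, tn + fp)
  f1 <- if (!is.na(pre) && !is.na(recall) && pre + recall > 0)
    2 * pre * recall / (pre + recall) else NA_real_
  out <- list(acc = acc, pre = pre, recall = recall, spe = spe, f1 = f1)
  out$undefined <- names(out)[vapply(out, is.na, logical(1))]
  out
}

#' Reader precision from counts
#'
#' @param correct number of correctly read images.
#' @param total number of images read.
#' @return percentage `100 * correct / total`.
#' @examples
#' precisionFromCounts(181, 200)  # 90.5
#' @export
precisionFromCounts <- function(correct, total) {
  if (total <= 0 || correct < 0 || correct > total)
    stop("need 0 <= correct <= total with total > 0; got ", correct, "/", total)
  100 * correct / total
}

#' ROC curve and AUC
#'
#' Threshold-sweep ROC with tied scores collapsed into single steps
#' (diagonal segments), integrated by the trapezoid rule; this equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, with ties counting one half.
#'
#' @param labels 0/1 vector, both classes present.
#' @param scores numeric scores, higher = more positive.
#' @return `ROCCurve` list: `points` (data frame `fpr`, `tpr` from (0,0) to
#'   (1,1)) and `auc`.
#' @examples
#' rocAuc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2))$auc  # 0.75
#' @export
rocAuc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0) stop("no positive cases in labels")
  if (nNeg == 0) stop("no negative cases in labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cutIdx <- which(diff(s) != 0)
  ends <- c(cutIdx, length(s))
  tpr <- c(0, cumsum(l == 1)[ends] / nPos)
  fpr <- c(0, cumsum(l == 0)[ends] / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "ROCCurve")
}

#' @export
print.ROCCurve <- function(x, ...) {
  cat(sprintf("ROCCurve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Localization hit scoring
#'
#' A localization is a hit when the argmax of the map (upsampled to the mask
#' resolution; ties broken by the first index in column-major raster order)
#' falls inside the lesion mask dilated by `dilatePx` pixels (Euclidean
#' disc).
#'
#' @param map a [LocalizationMap-class] or a matrix.
#' @param mask binary lesion mask; must be nonempty.
#' @param dilatePx dilation radius in mask pixels (default 9).
#' @return logical hit flag.
#' @export
localizationScore <- function(map, mask, dilatePx = 9) {
  if (is(map, "LocalizationMap")) map <- map@values
  fg <- which(mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("lesion mask is empty")
  if (!identical(dim(map), dim(mask)))
    map <- resizeBilinear(map, nrow(mask), ncol(mask))
  peak <- arrayInd(which.max(map), dim(map))
  min((fg[, 1] - peak[1])^2 + (fg[, 2] - peak[2])^2) <= dilatePx^2
}

#' Cross-validate a classifier over stratified folds
#'
#' For fold j the model is trained on the other k-1 folds and tested on fold
#' j; the report carries per-fold metrics and their arithmetic mean. AUC is
#' reported `NA` and flagged for a fold whose test set holds a single class.
#'
#' @param labels 0/1 labels for all cases.
#' @param trainFun `function(trainIdx)` returning a fitted model.
#' @param scoreFun `function(model, testIdx)` returning injury scores in
#'   [0, 1] for the test cases.
#' @param k,seed fold protocol parameters.
#' @param threshold decision threshold (ties positive).
#' @return `MetricsReport` data frame: one row per fold plus a `mean` row,
#'   columns `acc, pre, recall, spe, f1, auc` and the confusion counts.
#' @export
crossValidate <- function(labels, trainFun, scoreFun, k = 5L, seed = 1L,
                          threshold = 0.5) {
  fs <- makeFolds(labels, k = k, seed = seed)
  rows <- lapply(seq_len(k), function(j) {
    testIdx <- fs$folds[[j]]
    trainIdx <- setdiff(seq_along(labels), testIdx)
    model <- trainFun(trainIdx)
    scores <- scoreFun(model, testIdx)
    pred <- as.integer(scores >= threshold)
    cts <- countsFromPredictions(labels[testIdx], pred)
    m <- computeMetrics(cts)
    auc <- if (length(unique(labels[testIdx])) == 2L)
      rocAuc(labels[testIdx], scores)$auc else NA_real_
    data.frame(fold = names(fs$folds)[j], acc = m$acc, pre = m$pre,
               recall = m$recall, spe = m$spe, f1 = m$f1, auc = auc,
               tp = cts@tp, tn = cts@tn, fp = cts@fp, fn = cts@fn)
  })
  perFold <- do.call(rbind, rows)
  meanRow <- data.frame(fold = "mean", t(colMeans(perFold[, -1], na.rm = TRUE)))
  report <- rbind(perFold, meanRow)
  attr(report, "aucUndefinedFolds") <-
    perFold$fold[is.na(perFold$auc)]
  class(report) <- c("MetricsReport", "data.frame")
  report
}

#' Cross-validate the cascade itself on phantom cases
#'
#' Convenience wrapper running [trainCascade()] / [predictCascade()] inside
#' [crossValidate()].
#'
#' @param cases list of [PhantomCase-class].
#' @param config cascade configuration.
#' @param k,seed fold protocol parameters.
#' @export
crossValidateCascade <- function(cases, config = tinyCascadeConfig(),
                                 k = 5L, seed = 1L) {
  labels <- vapply(cases, caseLabel, integer(1))
  crossValidate(labels,
                trainFun = function(idx) {
                  cfg <- config
                  cfg$seed <- streamSeed(seed, cfg$seed)
                  trainCascade(cases[idx], cfg)
                },
                scoreFun = function(model, idx)
                  predictCascade(model, cases[idx])$prob,
                k = k, seed = seed, threshold = config$threshold)
}

#' Write a metrics report and ROC points as CSV
#'
#' @param report a `MetricsReport` from [crossValidate()].
#' @param dir output directory.
#' @param roc optional `ROCCurve` to write alongside.
#' @export
writeMetricsReport <- function(report, dir, roc = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report, file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(roc))
    utils::write.csv(roc$points, file.path(dir, "roc_points.csv"),
                     row.names = FALSE)
  invisible(file.path(dir, "metrics.csv"))
}
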