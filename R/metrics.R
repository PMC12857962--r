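## Evaluation metrics for binary interaction prediction: accuracy,
## precision, recall, F1 at a threshold; rank-based AUC with tie
## halving; step-interpolated average precision.

#' Area under the ROC curve
#'
#' The probability that a uniformly random positive is ranked above a
#' uniformly random negative, ties counted 1/2. Computed from ranks in
#' O(n log n); equals the exhaustive concordance count exactly.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 labels.
#' @return AUC in [0,1]; NaN (with a warning) if one class is absent.
#' @export
aucScore <- function(scores, labels) {
  pos <- labels == 1
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) {
    warning("AUC undefined: only one class present")
    return(NaN)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step interpolation: AP = sum over descending-score positives of
#' precision at that cut times the recall increment. Tied scores are
#' grouped (the cut falls after the whole tie group).
#'
#' @inheritParams aucScore
#' @return AP in [0,1]; NaN if there is no positive.
#' @export
apScore <- function(scores, labels) {
  nP <- sum(labels == 1)
  if (nP == 0 || nP == length(labels)) {
    warning("AP undefined: only one class present")
    return(NaN)
  }
  ## group tied scores: evaluate precision/recall after each group
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  groups <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  k <- seq_along(y)
  lastOfGroup <- which(groups != c(groups[-1], -1))
  prec <- tp[lastOfGroup] / k[lastOfGroup]
  rec <- tp[lastOfGroup] / nP
  sum(prec * diff(c(0, rec)))
}

#' Full metrics report for labeled predictions
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 labels.
#' @param threshold classification cut for ACC/precision/recall/F1
#'   (default 0.5).
#' @return list: ACC, AUC, F1, precision, recall, AP, TP/TN/FP/FN,
#'   threshold, n.
#' @export
evaluatePredictions <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  yhat <- as.integer(scores >= threshold)
  tp <- sum(yhat == 1 & labels == 1)
  tn <- sum(yhat == 0 & labels == 0)
  fp <- sum(yhat == 1 & labels == 0)
  fn <- sum(yhat == 0 & labels == 1)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  oneClass <- length(unique(labels)) < 2
  if (oneClass) {
    warning("only one class present: AUC and AP reported as NaN")
  }
  list(
    ACC = (tp + tn) / length(labels),
    AUC = if (oneClass) NaN else aucScore(scores, labels),
    F1 = f1, precision = prec, recall = rec,
    AP = if (oneClass) NaN else apScore(scores, labels),
    TP = tp, TN = tn, FP = fp, FN = fn,
    threshold = threshold, n = length(labels)
  )
}
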