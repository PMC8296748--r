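#' Confusion counts from labels and scores
#'
#' The positive class (label 1, e.g. the patient group) defines TP/FN;
#' the negative class (label 0) defines TN/FP.
#'
#' @param labels 0/1 true labels.
#' @param scores predicted positive-class probabilities (or any score).
#' @param threshold decision threshold on the score (default 0.5; a score
#'   strictly above it predicts class 1).
#' @return List with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  pred <- as.integer(scores > threshold)
  labels <- as.integer(labels)
  list(TP = sum(pred == 1 & labels == 1),
       FP = sum(pred == 1 & labels == 0),
       TN = sum(pred == 0 & labels == 0),
       FN = sum(pred == 0 & labels == 1))
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' Midranks handle tied scores, making the value equal to the trapezoidal
#' integral of the empirical ROC curve.
#'
#' @param labels 0/1 true labels (both classes must be present).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_rank <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metric suite
#'
#' Computes the six evaluation metrics used throughout the package:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total, F1 = 2TP/(2TP+FP+FN), Matthews correlation coefficient
#' (with the 0/0 limit defined as 0), and rank-based AUC.
#'
#' @param labels 0/1 true labels.
#' @param scores predicted positive-class probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return Named numeric vector with elements `accuracy`, `sensitivity`,
#'   `specificity`, `f1`, `auc`, `mcc`.
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6))
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  cc <- confusion_counts(labels, scores, threshold)
  c(metrics_from_counts(cc), auc = auc_rank(labels, scores))[
    c("accuracy", "sensitivity", "specificity", "f1", "auc", "mcc")]
}

#' Metrics from explicit confusion counts
#'
#' @param cc list with `TP`, `FP`, `TN`, `FN` (see [confusion_counts()]).
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `f1`, `mcc`. Undefined ratios (zero denominators) yield `NA` except
#'   MCC, whose degenerate denominator is defined as 0.
#' @export
metrics_from_counts <- function(cc) {
  TP <- cc$TP; FP <- cc$FP; TN <- cc$TN; FN <- cc$FN
  total <- TP + FP + TN + FN
  if (total == 0) stopf("empty confusion table")
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
  c(accuracy = (TP + TN) / total,
    sensitivity = div(TP, TP + FN),
    specificity = div(TN, TN + FP),
    f1 = div(2 * TP, 2 * TP + FP + FN),
    mcc = mcc)
}
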