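# Binary-classification metric suite: confusion counts, the six
# threshold-based metrics (Sen, Spe, Acc, MCC, Pre, F1), rank-based AUC,
# the precision-recall curve, and Cohen's kappa in its general multi-class
# form. Degenerate denominators return 0 with a warning rather than NaN.

#' Confusion-matrix counts
#'
#' @param y_true,y_pred Equal-length binary vectors; class 1 is positive.
#' @return List of class `confusion_counts` with TP, TN, FP, FN.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 1L) stop("empty input")
  structure(
    list(TP = sum(y_true == 1 & y_pred == 1),
         TN = sum(y_true == 0 & y_pred == 0),
         FP = sum(y_true == 0 & y_pred == 1),
         FN = sum(y_true == 1 & y_pred == 0)),
    class = "confusion_counts"
  )
}

.safe_div <- function(num, den, what) {
  if (den == 0) {
    warning(what, " has an empty denominator; returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Threshold-based binary metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy, Matthews
#' correlation coefficient, precision TP/(TP+FP) and F1 = 2TP/(2TP+FP+FN),
#' computed literally from the counts. Any metric whose denominator is
#' empty is reported as 0 with a warning.
#'
#' @param counts `confusion_counts`.
#' @return Named list: sen, spe, acc, mcc, pre, f1.
#' @export
binary_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  n <- TP + TN + FP + FN
  if (n == 0) stop("no samples")
  mcc_den <- sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TP + FP) * sqrt(TN + FN)
  list(
    sen = .safe_div(TP, TP + FN, "sensitivity"),
    spe = .safe_div(TN, TN + FP, "specificity"),
    acc = (TP + TN) / n,
    mcc = .safe_div(TP * TN - FP * FN, mcc_den, "MCC"),
    pre = .safe_div(TP, TP + FP, "precision"),
    f1 = .safe_div(2 * TP, 2 * TP + FP + FN, "F1")
  )
}

#' Rank-based AUC
#'
#' The area under the ROC curve computed as the Mann-Whitney statistic
#' with midranks for tied scores: the probability that a random positive
#' outscores a random negative (ties counting one half).
#'
#' @param y_true Binary labels (both classes present).
#' @param scores Real-valued scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) stop("AUC undefined: one class absent")
  r <- rank(scores)  # midranks under ties
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall curve
#'
#' Precision and recall at every distinct score threshold, in descending
#' threshold order, anchored at recall 0 (precision of the first point).
#'
#' @param y_true Binary labels (positives present).
#' @param scores Real-valued scores.
#' @return data.frame with columns threshold, recall, precision; recall is
#'   non-decreasing.
#' @export
pr_curve <- function(y_true, scores) {
  if (sum(y_true == 1) == 0) stop("no positive samples")
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y_true == 1)
  rows <- lapply(ths, function(t) {
    pred_pos <- scores >= t
    tp <- sum(pred_pos & y_true == 1)
    data.frame(threshold = t, recall = tp / n_pos,
               precision = if (sum(pred_pos) == 0) 1 else
                 tp / sum(pred_pos))
  })
  curve <- do.call(rbind, rows)
  # stop once every positive is recovered: later (lower) thresholds only
  # dilute precision at the same recall
  stop_at <- which(curve$recall == max(curve$recall))[1]
  curve <- curve[seq_len(stop_at), , drop = FALSE]
  rbind(data.frame(threshold = Inf, recall = 0,
                   precision = curve$precision[1]), curve)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(Acc - p_e) / (1 - p_e)` with
#' `p_e = sum_m a_m * b_m / n^2`, where a_m and b_m are the actual and
#' predicted counts of class m. Implemented over arbitrary label sets, so
#' the binary case is a specialization rather than an assumption. When
#' `p_e = 1` (both vectors constant), kappa is defined as 1 for identical
#' vectors and 0 otherwise, with a warning.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  n <- length(y_true)
  if (n < 1L) stop("empty input")
  classes <- sort(unique(c(y_true, y_pred)))
  a <- vapply(classes, function(cl) sum(y_true == cl), numeric(1))
  b <- vapply(classes, function(cl) sum(y_pred == cl), numeric(1))
  acc <- mean(y_true == y_pred)
  pe <- sum(a * b) / n^2
  if (pe == 1) {
    warning("degenerate kappa: both vectors constant", call. = FALSE)
    return(if (all(y_true == y_pred)) 1 else 0)
  }
  (acc - pe) / (1 - pe)
}

#' Full metrics report for one evaluation
#'
#' @param y_true Binary labels.
#' @param prediction A `prediction_result` (or a list with `scores` and
#'   `labels`).
#' @return List of class `metrics_report`: sen, spe, acc, mcc, pre, f1,
#'   auc, kappa, and the underlying `counts`.
#' @export
metrics_report <- function(y_true, prediction) {
  counts <- confusion_counts(y_true, prediction$labels)
  out <- binary_metrics(counts)
  out$auc <- roc_auc(y_true, prediction$scores)
  out$kappa <- cohen_kappa(y_true, prediction$labels)
  out$counts <- counts
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Sen %.4f  Spe %.4f  Acc %.4f  MCC %.4f\nPre %.4f  F1  %.4f  AUC %.4f  Kappa %.4f\n",
    x$sen, x$spe, x$acc, x$mcc, x$pre, x$f1, x$auc, x$kappa))
  invisible(x)
}
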