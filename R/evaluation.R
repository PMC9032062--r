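#' Confusion counts of a binary classifier
#'
#' @param labels true 0/1 labels.
#' @param predictions predicted 0/1 labels, same length.
#' @return list of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("`labels` and `predictions` must have equal length", call. = FALSE)
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (!all(labels %in% 0:1) || !all(predictions %in% 0:1))
    stop("labels and predictions must be binary (0/1)", call. = FALSE)
  structure(list(TP = sum(labels == 1L & predictions == 1L),
                 FP = sum(labels == 0L & predictions == 1L),
                 TN = sum(labels == 0L & predictions == 0L),
                 FN = sum(labels == 1L & predictions == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), specificity and the Matthews
#' correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' Degenerate cases follow the convention that a zero factor in the MCC
#' denominator yields MCC = 0 (a classifier that ignores its input carries no
#' correlation), and an undefined precision/recall/specificity (zero
#' denominator) is reported as 0 with `degenerate = TRUE`.
#'
#' @param cc a `confusion_counts` (or list with TP/FP/TN/FN).
#' @return list of class `eval_metrics`: `accuracy`, `precision`, `recall`,
#'   `specificity` (fractions), `mcc`, `degenerate`.
#' @export
classification_metrics <- function(cc) {
  TP <- cc$TP; FP <- cc$FP; TN <- cc$TN; FN <- cc$FN
  n <- TP + FP + TN + FN
  if (n <= 0) stop("empty confusion matrix", call. = FALSE)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  acc <- (TP + TN) / n
  prec <- safe_div(TP, TP + FP)
  rec <- safe_div(TP, TP + FN)
  spec <- safe_div(TN, TN + FP)
  den2 <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den2 == 0) { degenerate <- TRUE; 0 } else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den2)
  structure(list(accuracy = acc, precision = prec, recall = rec,
                 specificity = spec, mcc = mcc, degenerate = degenerate),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  recall %.2f%%  specificity %.2f%%  MCC %.3f%s\n",
              100 * x$accuracy, 100 * x$precision, 100 * x$recall,
              100 * x$specificity, x$mcc,
              if (x$degenerate) "  (degenerate)" else ""))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores; the area under the
#' curve is computed by the trapezoid rule and equals the Mann-Whitney rank
#' statistic (probability that a random positive outscores a random
#' negative, ties counting one half).
#'
#' @param labels true 0/1 labels (both classes must be present).
#' @param scores classifier scores/probabilities.
#' @return list of class `roc_result`: `points` (data.frame `fpr`, `tpr`,
#'   `threshold`, starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores))
    stop("`labels` and `scores` must have equal length", call. = FALSE)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("ROC needs both classes present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tpr[i] <- sum(pred & labels == 1L) / P
    fpr[i] <- sum(pred & labels == 0L) / N
  }
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    threshold = c(Inf, thr, -Inf))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc> %d points, AUC = %.3f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Evaluate predictions end to end
#'
#' Convenience wrapper: thresholds scores at `threshold`, tabulates the
#' confusion matrix and derives all scalar metrics plus ROC/AUC.
#'
#' @param labels true 0/1 labels.
#' @param scores classifier probabilities.
#' @param threshold decision threshold (default 0.5, prediction positive when
#'   score >= threshold).
#' @return `eval_metrics` list extended with `auc` and `confusion`.
#' @export
evaluate_predictions <- function(labels, scores, threshold = 0.5) {
  cc <- confusion(labels, as.integer(scores >= threshold))
  m <- classification_metrics(cc)
  m$auc <- if (length(unique(labels)) == 2L) roc_auc(labels, scores)$auc else NA_real_
  m$confusion <- cc
  m
}
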