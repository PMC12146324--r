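#' Confusion-matrix classification metrics
#'
#' Computes the six threshold-based metrics of the evaluation harness
#' from confusion-matrix counts (positive class = cytoplasm throughout):
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/total`, Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` and
#' F1 `TP / (TP + 0.5*(FN+FP))`. Undefined `0/0` cases (e.g. precision
#' with no positive predictions, or a zero MCC radical) are reported as
#' 0, matching the convention of degenerate all-negative classifiers.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A one-row tibble with columns `sens`, `spec`, `prec`, `acc`,
#'   `mcc`, `f1`.
#' @examples
#' confusion_metrics(30, 10, 40, 20)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative",
                            call. = FALSE)
  if (sum(counts) < 1) stop("empty confusion matrix", call. = FALSE)
  radical <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  tibble::tibble(
    sens = safe_div(tp, tp + fn),
    spec = safe_div(tn, tn + fp),
    prec = safe_div(tp, tp + fp),
    acc = (tp + tn) / sum(counts),
    mcc = safe_div(tp * tn - fp * fn, radical),
    f1 = safe_div(tp, tp + 0.5 * (fn + fp))
  )
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation of AUC: the probability that a random
#' positive scores above a random negative, with ties contributing 1/2.
#'
#' @param labels Logical vector (or coercible) marking positives.
#' @param scores Numeric prediction scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores), !anyNA(labels),
            all(is.finite(scores)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("undefined AUC: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# full seven-metric set from labels, scores and a threshold
metric_set <- function(truth_pos, scores, threshold = 0.5) {
  pred_pos <- scores >= threshold
  m <- confusion_metrics(tp = sum(pred_pos & truth_pos),
                         fp = sum(pred_pos & !truth_pos),
                         tn = sum(!pred_pos & !truth_pos),
                         fn = sum(!pred_pos & truth_pos))
  m$auc <- auc_score(truth_pos, scores)
  m
}
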