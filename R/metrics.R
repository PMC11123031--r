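#' Binary-classification metrics from predicted and true labels
#'
#' Computes accuracy, precision, recall, F1 and the Matthews correlation
#' coefficient from the full confusion matrix. MCC:
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' Any zero factor in the denominator yields MCC = 0 by convention;
#' precision, recall and F1 with a zero denominator are likewise 0.
#'
#' @param predicted,truth Equal-length vectors of 0/1 labels.
#' @return A `metric_set`: named list with `accuracy`, `precision`,
#'   `recall`, `f1` in \[0, 1\] and `mcc` in \[-1, 1\].
#' @examples
#' compute_metrics(c(1, 0, 1, 0), c(1, 0, 0, 0))
#' @export
compute_metrics <- function(predicted, truth) {
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (length(predicted) != length(truth) || length(truth) < 1L) {
    stop_pathpair("predicted and truth must have equal length >= 1",
                  "pathpair_shape_error")
  }
  tp <- sum(predicted == 1L & truth == 1L)
  tn <- sum(predicted == 0L & truth == 0L)
  fp <- sum(predicted == 1L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  n <- tp + tn + fp + fn
  accuracy <- (tp + tn) / n
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  } else 0
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, mcc = mcc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  mcc %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$mcc))
  invisible(x)
}
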