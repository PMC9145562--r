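# Confusion-matrix performance measures, including the multiclass
# generalization of the Matthews correlation coefficient.

#' Multiclass Matthews correlation coefficient
#'
#' Computed from the full k x k confusion matrix (rows = truth, columns =
#' prediction) as
#' \deqn{\frac{c\,s - \sum_k p_k t_k}
#'   {\sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}},}
#' with `c` the number of correct predictions, `s` the total, and `t_k`,
#' `p_k` the true and predicted counts of class k. Reduces exactly to the
#' familiar binary MCC on 2 x 2 matrices. A zero denominator (e.g. a single
#' predicted class) yields 0.
#'
#' @param confusion Square matrix of non-negative counts.
#' @return MCC in `[-1, 1]`.
#' @export
#' @examples
#' mcc(matrix(c(3, 2, 1, 4), 2))
mcc <- function(confusion) {
  m <- as.matrix(confusion)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  s <- sum(m)
  if (s == 0) abort("confusion matrix is all zero", "antmorph_validation_error")
  c_ <- sum(diag(m))
  t_k <- rowSums(m)
  p_k <- colSums(m)
  num <- c_ * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' Classification performance measures from a confusion matrix
#'
#' Accuracy is the trace over the total. Precision, sensitivity and
#' specificity are computed one-vs-rest per class and aggregated by
#' macro-averaging (default) or micro-averaging (pooling the per-class
#' counts); per-class values that are undefined (zero denominator) are
#' dropped from the macro mean. The MCC is the multiclass [mcc()].
#'
#' @param confusion Square count matrix, rows = truth, columns = prediction.
#' @param average `"macro"` or `"micro"`.
#' @return Named numeric: accuracy, precision, sensitivity, specificity, mcc.
#' @export
#' @examples
#' classification_metrics(diag(5, 3))
classification_metrics <- function(confusion, average = c("macro", "micro")) {
  average <- match.arg(average)
  m <- as.matrix(confusion)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  total <- sum(m)
  if (total == 0) abort("confusion matrix is all zero", "antmorph_validation_error")
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- total - tp - fn - fp
  if (average == "macro") {
    precision <- mean((tp / (tp + fp))[tp + fp > 0])
    sensitivity <- mean((tp / (tp + fn))[tp + fn > 0])
    specificity <- mean((tn / (tn + fp))[tn + fp > 0])
  } else {
    precision <- sum(tp) / sum(tp + fp)
    sensitivity <- sum(tp) / sum(tp + fn)
    specificity <- sum(tn) / sum(tn + fp)
  }
  c(accuracy = sum(tp) / total,
    precision = precision,
    sensitivity = sensitivity,
    specificity = specificity,
    mcc = mcc(m))
}
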