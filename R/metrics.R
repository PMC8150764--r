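#' F1 score from confusion counts
#'
#' Harmonic mean of precision and recall: `2 * p * r / (p + r)`, defined as
#' 0 when precision + recall is 0.
#'
#' @param tp,fp,fn True-positive, false-positive and false-negative counts.
#' @return F1 in [0, 1].
#' @export
f1_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop_input("counts must be non-negative")
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Balanced accuracy from confusion counts
#'
#' Mean of sensitivity and specificity; requires both classes present.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return Balanced accuracy in [0, 1].
#' @export
balanced_accuracy <- function(tp, fp, tn, fn) {
  if (tp + fn == 0 || tn + fp == 0) {
    stop_input("balanced accuracy undefined: a class is absent")
  }
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Area under the ROC curve
#'
#' Rank statistic: the probability that a random positive scores above a
#' random negative, counting ties as one half (equivalently the
#' trapezoidal area under the ROC curve).
#'
#' @param scores Numeric classifier scores, larger meaning more positive.
#' @param labels Logical (or coercible) vector, `TRUE` for positives.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop_input("AUC undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Root mean square error
#'
#' @param predicted,observed Aligned numeric vectors (METs for the energy
#'   expenditure task).
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0) stop_input("empty input")
  if (length(predicted) != length(observed)) {
    stop_input("predicted and observed must have equal length")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Macro-averaged F1
#'
#' Unweighted mean of per-class F1 scores.
#'
#' @param per_class_f1 Numeric vector of per-class F1 values; `NA`s are
#'   dropped with a warning (a class absent from the evaluation fold).
#' @return Mean F1.
#' @export
macro_f1 <- function(per_class_f1) {
  if (length(per_class_f1) == 0) stop_input("empty input")
  if (anyNA(per_class_f1)) {
    warning("dropping undefined per-class F1 values", call. = FALSE)
    per_class_f1 <- per_class_f1[!is.na(per_class_f1)]
  }
  mean(per_class_f1)
}

# per-class F1 from a K x K confusion matrix (rows = truth, cols = predicted)
.per_class_f1 <- function(cm) {
  vapply(seq_len(nrow(cm)), function(i) {
    f1_score(tp = cm[i, i], fp = sum(cm[-i, i]), fn = sum(cm[i, -i]))
  }, numeric(1))
}
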