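# Confusion counts and classification metrics.

#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp = 0, tn = 0, fp = 0, fn = 0) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(is.na(v)) || any(v < 0) || any(!is.finite(v))) {
    stop("confusion counts must be finite and non-negative")
  }
  structure(as.list(as.numeric(v)), names = names(v), class = "confusion_counts")
}

#' Tally confusion counts from predictions
#'
#' @param pred,truth Binary vectors (0/1 or logical) of equal length.
#' @return A [confusion_counts()].
#' @export
tally_confusion <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  pred <- as.integer(pred); truth <- as.integer(truth)
  confusion_counts(tp = sum(pred == 1L & truth == 1L),
                   tn = sum(pred == 0L & truth == 0L),
                   fp = sum(pred == 1L & truth == 0L),
                   fn = sum(pred == 0L & truth == 1L))
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, defined as 0 when
#' any denominator factor is zero. Robust to class imbalance; in `[-1, 1]`.
#'
#' @param c A [confusion_counts()].
#' @return Numeric scalar.
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  f1 <- tp + fp; f2 <- tp + fn; f3 <- tn + fp; f4 <- tn + fn
  if (f1 == 0 || f2 == 0 || f3 == 0 || f4 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(f1 * f2 * f3 * f4)
}

#' Companion classification metrics
#'
#' F1, precision, recall and accuracy with the 0/0 -> 0 convention.
#'
#' @param c A [confusion_counts()].
#' @return Named numeric vector `f1`, `precision`, `recall`, `accuracy`.
#' @export
companion_metrics <- function(c) {
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  div0 <- function(num, den) if (den == 0) 0 else num / den
  precision <- div0(tp, tp + fp)
  recall <- div0(tp, tp + fn)
  f1 <- div0(2 * precision * recall, precision + recall)
  accuracy <- div0(tp + tn, tp + tn + fp + fn)
  c(f1 = f1, precision = precision, recall = recall, accuracy = accuracy)
}

.metric_row <- function(c) {
  cm <- companion_metrics(c)
  data.frame(mcc = mcc(c), f1 = cm[["f1"]], precision = cm[["precision"]],
             recall = cm[["recall"]], accuracy = cm[["accuracy"]],
             tp = c$tp, tn = c$tn, fp = c$fp, fn = c$fn)
}
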