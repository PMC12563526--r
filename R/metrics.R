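#' Confusion counts with FM as the positive class
#'
#' @param pred,truth factors (or characters) with levels `FM` / `N-FM`.
#' @param positive the positive-class label.
#' @return object of class `fm_confusion`: list with `tp`, `tn`, `fp`,
#'   `fn`; the four counts sum to the number of evaluated segments.
#' @export
confusion_counts <- function(pred, truth, positive = "FM") {
  pred <- as.character(pred)
  truth <- as.character(truth)
  stopifnot(length(pred) == length(truth))
  structure(list(
    tp = sum(pred == positive & truth == positive),
    tn = sum(pred != positive & truth != positive),
    fp = sum(pred == positive & truth != positive),
    fn = sum(pred != positive & truth == positive)
  ), class = "fm_confusion")
}

#' Sensitivity, precision and F1 (percent)
#'
#' `SEN = TP / (TP + FN)`, `PRE = TP / (TP + FP)`, and F1 is their harmonic
#' mean; all reported as percentages. A ratio with an empty denominator is
#' undefined and reported as `NA`, never silently as zero, so that
#' aggregation over repeats cannot be corrupted by degenerate splits.
#'
#' @param counts an `fm_confusion` (or a list with tp/tn/fp/fn).
#' @return list with numeric `SEN`, `PRE`, `F1` in percent (possibly `NA`).
#' @export
fm_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  pre <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sen) && !is.na(pre) && (sen + pre) > 0)
    2 * pre * sen / (pre + sen) else NA_real_
  list(SEN = sen, PRE = pre, F1 = f1)
}
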