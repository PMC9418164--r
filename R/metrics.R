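# Evaluation: Dice, Jaccard, pixel accuracy, recall and precision on
# binarized predictions, macro-averaged over images.

metric_row <- function(pred, truth, threshold) {
  p <- pred >= threshold
  t <- truth >= 0.5
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  # empty-denominator convention: score 1 when the prediction agrees that the
  # set is empty, else 0
  safe <- function(num, den, empty_ok) if (den == 0) as.numeric(empty_ok) else num / den
  both_empty <- (tp + fp + fn) == 0
  data.frame(dice = safe(2 * tp, 2 * tp + fp + fn, both_empty),
             jaccard = safe(tp, tp + fp + fn, both_empty),
             accuracy = (tp + tn) / length(p),
             recall = safe(tp, tp + fn, fp == 0),
             precision = safe(tp, tp + fp, fn == 0))
}

#' Evaluate segmentation predictions
#'
#' Predictions are binarized at `threshold`; per-image confusion counts give
#' Dice `2TP/(2TP+FP+FN)`, Jaccard `TP/(TP+FP+FN)`, accuracy, recall and
#' precision, then scores are macro-averaged over images.  An image whose
#' denominator is empty scores 1 when the prediction is empty too, else 0.
#'
#' @param pred_maps List of probability maps (or an `H x W x n` array).
#' @param truths List of binary masks (or an `H x W x n` array).
#' @param threshold Binarization threshold in `(0, 1)`, default 0.5.
#' @return An `eval_result` list: the five macro scores, `n_images`,
#'   `threshold`, and a `per_image` data frame.
#' @export
evaluate <- function(pred_maps, truths, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  as_list <- function(x) {
    if (is.list(x)) return(x)
    d <- dim(x)
    if (length(d) == 2L) return(list(x))
    lapply(seq_len(d[3]), function(i) x[, , i])
  }
  pred_maps <- as_list(pred_maps); truths <- as_list(truths)
  if (length(pred_maps) != length(truths))
    stopf("got %d predictions but %d truths", length(pred_maps), length(truths))
  if (length(pred_maps) == 0L) stopf("nothing to evaluate")
  rows <- do.call(rbind, Map(function(p, t) {
    if (!identical(dim(p), dim(t))) stopf("prediction/truth shape mismatch")
    metric_row(p, t, threshold)
  }, pred_maps, truths))
  structure(list(dice = mean(rows$dice), jaccard = mean(rows$jaccard),
                 accuracy = mean(rows$accuracy), recall = mean(rows$recall),
                 precision = mean(rows$precision),
                 n_images = length(pred_maps), threshold = threshold,
                 per_image = rows),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "Segmentation evaluation over %d image(s) (threshold %.2f)\n", x$n_images,
    x$threshold))
  cat(sprintf("  Dice %.4f | Jaccard %.4f | Accuracy %.4f | Recall %.4f | Precision %.4f\n",
              x$dice, x$jaccard, x$accuracy, x$recall, x$precision))
  invisible(x)
}

eval_result_row <- function(ev) {
  data.frame(dice = ev$dice, jaccard = ev$jaccard, accuracy = ev$accuracy,
             recall = ev$recall, precision = ev$precision)
}
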