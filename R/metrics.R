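#' Per-class confusion counts
#'
#' One-vs-rest confusion counts for a multi-class problem: for each class
#' c, TP (labelled c, predicted c), FP (not c, predicted c), FN (labelled
#' c, predicted otherwise) and TN (the rest).  Rows sum to the number of
#' samples; the TP column sums to the number of correct predictions.
#'
#' @param predictions,labels Equal-length vectors of class indices in
#'   `1..n_classes`.
#' @param n_classes Number of classes.
#' @return `n_classes x 4` integer matrix with columns TP, FP, FN, TN.
#' @export
confusion_counts <- function(predictions, labels, n_classes) {
  if (length(predictions) != length(labels)) {
    stop("confusion_counts: predictions and labels differ in length")
  }
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  if (any(predictions < 1L | predictions > n_classes) ||
      any(labels < 1L | labels > n_classes)) {
    stop("confusion_counts: class index outside 1..", n_classes)
  }
  total <- length(labels)
  counts <- matrix(0L, nrow = n_classes, ncol = 4L,
                   dimnames = list(NULL, c("TP", "FP", "FN", "TN")))
  for (c_ in seq_len(n_classes)) {
    tp <- sum(predictions == c_ & labels == c_)
    fp <- sum(predictions == c_ & labels != c_)
    fn <- sum(predictions != c_ & labels == c_)
    counts[c_, ] <- c(tp, fp, fn, total - tp - fp - fn)
  }
  counts
}

#' Macro-averaged classification metrics
#'
#' Computes, from one-vs-rest confusion counts, per-class precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 (their harmonic mean,
#' `2PR/(P+R)`), macro-averages them unweighted over classes, and reports
#' overall accuracy `(TP+TN)/(TP+TN+FP+FN)` = correct/total.  A class with
#' a zero denominator contributes 0 to the macro average.
#'
#' @param counts Matrix from [confusion_counts()], or a list with
#'   `predictions`/`labels`/`n_classes`.
#' @return Object of class `"metrics_report"`: `per_class` data frame and
#'   scalar `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- confusion_counts(counts$predictions, counts$labels,
                               counts$n_classes)
  }
  tp <- counts[, "TP"]; fp <- counts[, "FP"]
  fn <- counts[, "FN"]; tn <- counts[, "TN"]
  total <- tp[1] + fp[1] + fn[1] + tn[1]
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  per_class <- data.frame(class = seq_len(nrow(counts)), TP = tp, FP = fp,
                          FN = fn, TN = tn, precision = precision,
                          recall = recall, f1 = f1)
  structure(
    list(per_class = per_class,
         accuracy = sum(tp) / total,
         precision = mean(precision),
         recall = mean(recall),
         f1 = mean(f1),
         n = total),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Classification metrics (%d samples, %d classes, macro-averaged):\n",
    x$n, nrow(x$per_class)))
  cat(sprintf("  accuracy  %.*f\n  precision %.*f\n  recall    %.*f\n  F1        %.*f\n",
              digits, x$accuracy, digits, x$precision,
              digits, x$recall, digits, x$f1))
  invisible(x)
}
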