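# Agreement between automatic and manual lesion masks: pixel confusion counts,
# XOR border error, precision, recall, and per-image batch reports.

#' Pixel confusion counts between two masks
#'
#' @param auto Automatic [binary_mask()].
#' @param manual Manual (ground-truth) [binary_mask()] of the same shape.
#' @return Named integer vector `c(tp, tn, fp, fn)`; the counts sum to the
#'   pixel total.
#' @export
confusion_counts <- function(auto, manual) {
  if (!identical(dim(auto), dim(manual)))
    stop("auto and manual masks must share one shape")
  a <- unclass(auto); g <- unclass(manual)
  tp <- sum(a & g)
  fp <- sum(a & !g)
  fn <- sum(!a & g)
  c(tp = tp, tn = length(a) - tp - fp - fn, fp = fp, fn = fn)
}

#' XOR border error
#'
#' `100 * Area(auto XOR manual) / Area(manual)`, equivalently
#' `100 * (FP + FN) / (TP + FN)`. Zero for identical masks, 100 for an empty
#' automatic mask, and unbounded above when false positives dominate.
#'
#' @inheritParams confusion_counts
#' @return Border error in percent.
#' @export
border_error <- function(auto, manual) {
  if (!identical(dim(auto), dim(manual)))
    stop("auto and manual masks must share one shape")
  denom <- mask_area(manual)
  if (denom == 0) stop("border error is undefined for an empty manual mask")
  100 * sum(xor(unclass(auto), unclass(manual))) / denom
}

#' Precision and recall from confusion counts
#'
#' Precision is the positive predictive value `TP / (TP + FP)`; recall the
#' sensitivity `TP / (TP + FN)`. A zero denominator yields `NA` (the metric is
#' undefined, not zero).
#'
#' @param counts Named vector from [confusion_counts()].
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Evaluate one automatic/manual mask pair
#'
#' @inheritParams confusion_counts
#' @param image_id Identifier for the report row.
#' @return One-row data frame: `image_id`, `tp`, `tn`, `fp`, `fn`,
#'   `border_error_pct`, `precision`, `recall`. Undefined metrics are `NA`.
#' @export
evaluate_pair <- function(auto, manual, image_id = "image") {
  counts <- confusion_counts(auto, manual)
  pr <- precision_recall(counts)
  be <- if (mask_area(manual) > 0) border_error(auto, manual) else NA_real_
  data.frame(image_id = as.character(image_id),
             tp = counts[["tp"]], tn = counts[["tn"]],
             fp = counts[["fp"]], fn = counts[["fn"]],
             border_error_pct = be,
             precision = unname(pr["precision"]),
             recall = unname(pr["recall"]),
             stringsAsFactors = FALSE)
}

#' Evaluate a batch of mask pairs
#'
#' @param pairs List; each element a list with `image_id`, `auto`, `manual`.
#' @return Data frame with one [evaluate_pair()] row per pair plus a final
#'   `"mean"` row holding the unweighted per-image means of border error,
#'   precision and recall. `NA` metrics are excluded from their column's mean
#'   and their count is reported in a message.
#' @export
batch_evaluate <- function(pairs) {
  if (length(pairs) == 0) stop("batch_evaluate needs at least one pair")
  rows <- do.call(rbind, lapply(pairs, function(p)
    evaluate_pair(p$auto, p$manual, p$image_id)))
  metric_cols <- c("border_error_pct", "precision", "recall")
  n_missing <- sum(is.na(rows[, metric_cols]))
  if (n_missing > 0)
    message(n_missing, " undefined metric value(s) excluded from the means")
  agg <- data.frame(image_id = "mean", tp = NA_integer_, tn = NA_integer_,
                    fp = NA_integer_, fn = NA_integer_,
                    border_error_pct = mean(rows$border_error_pct, na.rm = TRUE),
                    precision = mean(rows$precision, na.rm = TRUE),
                    recall = mean(rows$recall, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  rbind(rows, agg)
}

#' Write an evaluation report as CSV
#'
#' Columns `image_id, border_error_pct, precision, recall`; border error with
#' two decimals, precision and recall as two-decimal fractions. The library
#' API (the data frame) keeps full precision.
#'
#' @param report Data frame from [batch_evaluate()] or [evaluate_pair()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- data.frame(image_id = report$image_id,
                    border_error_pct = sprintf("%.2f", report$border_error_pct),
                    precision = sprintf("%.2f", report$precision),
                    recall = sprintf("%.2f", report$recall),
                    stringsAsFactors = FALSE)
  for (k in c("border_error_pct", "precision", "recall"))
    out[[k]][is.na(report[[k]])] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
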