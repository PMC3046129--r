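# Pixel-based evaluation of tumour vs non-tumour segmentation.
#
# Every pixel is scored against the ground truth (no object-level leniency).
# Ambiguous regions that even an experienced pathologist cannot call are
# excluded through a don't-care mask; ground-truth background pixels are
# excluded by default (the task is cancerous-cell segmentation), but can be
# scored as non-tumour instead.

#' Pixel confusion counts for tumour detection
#'
#' Positive class = tumour. Prediction labels 2 (non-tumour) and
#' 3 (background) both count as negative predictions; a 4-class prediction is
#' merged with [merge_non_tumour()] first. In the truth, label 1 is tumour,
#' background (4 in the 4-class coding, 3 in the merged coding) is handled per
#' `background`, and anything else is non-tumour.
#'
#' @param pred Predicted labelling: merged 3-class (1/2/3) or 4-class (1..4).
#' @param truth Ground-truth labelling, 4-class (1..4) or merged 3-class.
#' @param exclude Optional logical `H x W` don't-care mask (`TRUE` = excluded).
#' @param background `"exclude"` (default): ground-truth background pixels are
#'   not scored; `"non_tumour"`: they are scored as negatives.
#' @return List of class `confusion_counts`: `TP`, `FP`, `TN`, `FN`,
#'   `excluded` (all pixel counts; they sum to the raster size).
#' @export
confusion_counts <- function(pred, truth, exclude = NULL,
                             background = c("exclude", "non_tumour")) {
  background <- match.arg(background)
  if (!all(dim(pred) == dim(truth)))
    stop("prediction and truth rasters differ in shape", call. = FALSE)
  if (any(pred > 3L)) pred <- merge_non_tumour(pred)
  bg_code <- if (any(truth > 3L)) 4L else 3L
  excl <- if (is.null(exclude)) matrix(FALSE, nrow(truth), ncol(truth)) else {
    if (!all(dim(exclude) == dim(truth)))
      stop("exclusion mask shape mismatch", call. = FALSE)
    exclude
  }
  if (background == "exclude") excl <- excl | truth == bg_code
  use <- !excl
  p_pos <- pred == 1L
  t_pos <- truth == 1L
  counts <- list(
    TP = sum(use & p_pos & t_pos),
    FP = sum(use & p_pos & !t_pos),
    TN = sum(use & !p_pos & !t_pos),
    FN = sum(use & !p_pos & t_pos),
    excluded = sum(excl))
  structure(counts, class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `tp_rate = TP/(TP+FN)`,
#' `fn_rate = FN/(FN+TP)`, `tn_rate = TN/(TN+FP)`, `precision = TP/(TP+FP)`.
#' The false-positive rate is `FP/(FP+TN)` (the complement of the TN rate) by
#' default; `fp_rate = "vs_tp"` gives the `FP/(FP+TP)` variant instead. A
#' metric with a zero denominator is returned as `NA` rather than raising a
#' division error.
#'
#' @param counts A [confusion_counts()] result (or any list with TP/FP/TN/FN).
#' @param fp_rate `"complement"` (default, `FP/(FP+TN) = 1 - tn_rate`) or
#'   `"vs_tp"` (`FP/(FP+TP)`).
#' @return Named numeric vector: accuracy, tp_rate, fp_rate, fn_rate, tn_rate,
#'   precision.
#' @export
segmentation_metrics <- function(counts, fp_rate = c("complement", "vs_tp")) {
  fp_rate <- match.arg(fp_rate)
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(accuracy = div(tp + tn, tp + tn + fp + fn),
    tp_rate = div(tp, tp + fn),
    fp_rate = if (fp_rate == "complement") div(fp, fp + tn) else div(fp, fp + tp),
    fn_rate = div(fn, fn + tp),
    tn_rate = div(tn, tn + fp),
    precision = div(tp, tp + fp))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("pixel confusion: TP", x$TP, " FP", x$FP, " TN", x$TN, " FN", x$FN,
      " excluded", x$excluded, "\n")
  invisible(x)
}

#' Colour overlay of evaluation outcomes
#'
#' Builds the standard evaluation rendering: green = true positive,
#' red = true negative, yellow = false negative, blue = false positive;
#' excluded pixels are mid-grey.
#'
#' @inheritParams confusion_counts
#' @return `H x W x 3` numeric array of 0-255 intensities.
#' @export
evaluation_overlay <- function(pred, truth, exclude = NULL,
                               background = c("exclude", "non_tumour")) {
  background <- match.arg(background)
  if (any(pred > 3L)) pred <- merge_non_tumour(pred)
  bg_code <- if (any(truth > 3L)) 4L else 3L
  excl <- if (is.null(exclude)) matrix(FALSE, nrow(truth), ncol(truth)) else exclude
  if (background == "exclude") excl <- excl | truth == bg_code
  p_pos <- pred == 1L; t_pos <- truth == 1L
  cols <- rbind(TP = c(0, 255, 0), TN = c(255, 0, 0),
                FN = c(255, 255, 0), FP = c(0, 0, 255), EX = c(128, 128, 128))
  code <- matrix(0L, nrow(truth), ncol(truth))
  code[p_pos & t_pos] <- 1L
  code[!p_pos & !t_pos] <- 2L
  code[!p_pos & t_pos] <- 3L
  code[p_pos & !t_pos] <- 4L
  code[excl] <- 5L
  out <- array(0, c(nrow(truth), ncol(truth), 3L))
  for (ch in 1:3) out[, , ch] <- matrix(cols[code, ch], nrow(truth))
  out
}
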