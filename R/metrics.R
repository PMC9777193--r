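# Pixel-level evaluation: confusion counts and the five derived measures
# (accuracy, specificity, sensitivity, Jaccard/IoU, Dice), plus batch
# reports under both aggregation conventions.

#' Pixelwise confusion counts
#'
#' Tallies TP/TN/FP/FN between a predicted and a ground-truth mask; ulcer
#' (TRUE) is the positive class.
#'
#' @param pred,truth logical matrices of equal dimensions.
#' @return a list of class `confusion_counts` with fields `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(pred, truth) {
  check_mask(pred, arg = "pred")
  check_mask(truth, ref = pred, arg = "truth")
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- length(pred) - tp - fp - fn
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Computes, exactly as ratios of counts:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), specificity = TN/(TN+FP),
#' sensitivity = TP/(TP+FN), IoU (Jaccard) = TP/(TP+FP+FN),
#' Dice = 2TP/(2TP+FP+FN). Ratios with a zero denominator are reported as
#' `NA` (missing), not 0, so healthy-eye images do not silently drag
#' aggregate sensitivity.
#'
#' @param counts a [confusion()] result, or a list with fields TP/TN/FP/FN.
#' @return a list of class `metrics_report` with fields `accuracy`,
#'   `specificity`, `sensitivity`, `iou`, `dice`, `counts`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total <= 0) stop("empty confusion counts", call. = FALSE)
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(accuracy = rat(tp + tn, total),
                 specificity = rat(tn, tn + fp),
                 sensitivity = rat(tp, tp + fn),
                 iou = rat(tp, tp + fp + fn),
                 dice = rat(2 * tp, 2 * tp + fp + fn),
                 counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f | specificity %.4f | sensitivity %.4f",
                     " | IoU %.4f | Dice %.4f\n"),
              x$accuracy, x$specificity, x$sensitivity, x$iou, x$dice))
  invisible(x)
}

metrics_row <- function(m, id) {
  data.frame(id = id, accuracy = m$accuracy, specificity = m$specificity,
             sensitivity = m$sensitivity, iou = m$iou, dice = m$dice,
             TP = m$counts$TP, TN = m$counts$TN, FP = m$counts$FP,
             FN = m$counts$FN, stringsAsFactors = FALSE)
}

#' Batch evaluation of mask pairs
#'
#' Evaluates each (prediction, truth) pair and appends two aggregate rows:
#' `"pooled"` (metrics of the summed confusion counts) and `"mean"`
#' (mean of the per-image metrics, missing values dropped). Both conventions
#' are reported because dataset-level summaries differ between them whenever
#' image sizes or prevalences vary.
#'
#' @param preds,truths lists of logical matrices, pairwise of equal size.
#' @param ids character vector of image identifiers; defaults to names of
#'   `preds` or `img_1 ... img_n`.
#' @return a data frame, one row per image plus the two aggregate rows, with
#'   columns id, accuracy, specificity, sensitivity, iou, dice, TP, TN, FP,
#'   FN.
#' @export
evaluate_batch <- function(preds, truths, ids = NULL) {
  stopifnot(is.list(preds), is.list(truths), length(preds) >= 1L,
            length(preds) == length(truths))
  if (is.null(ids)) ids <- names(preds)
  if (is.null(ids)) ids <- sprintf("img_%d", seq_along(preds))
  rows <- vector("list", length(preds))
  for (i in seq_along(preds)) {
    cts <- tryCatch(confusion(preds[[i]], truths[[i]]), error = function(e)
      stop(sprintf("image '%s': %s", ids[i], conditionMessage(e)),
           call. = FALSE))
    rows[[i]] <- metrics_row(compute_metrics(cts), ids[i])
  }
  per_image <- do.call(rbind, rows)
  pooled <- compute_metrics(list(TP = sum(per_image$TP), TN = sum(per_image$TN),
                                 FP = sum(per_image$FP), FN = sum(per_image$FN)))
  pooled_row <- metrics_row(pooled, "pooled")
  mean_row <- data.frame(id = "mean",
                         accuracy = mean(per_image$accuracy, na.rm = TRUE),
                         specificity = mean(per_image$specificity, na.rm = TRUE),
                         sensitivity = mean(per_image$sensitivity, na.rm = TRUE),
                         iou = mean(per_image$iou, na.rm = TRUE),
                         dice = mean(per_image$dice, na.rm = TRUE),
                         TP = NA_integer_, TN = NA_integer_,
                         FP = NA_integer_, FN = NA_integer_,
                         stringsAsFactors = FALSE)
  out <- rbind(per_image, pooled_row, mean_row)
  rownames(out) <- NULL
  out
}
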