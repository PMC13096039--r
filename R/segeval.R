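# Pixel-level confusion counting and overlap metrics for binary masks.

#' Pixel-wise confusion counts between a predicted and a reference mask
#'
#' @param pred,truth 0/1 matrices of equal dimensions.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`
#'   (tp + fp + tn + fn = pixel count).
#' @export
confusion <- function(pred, truth) {
  check_mask(pred, "pred"); check_mask(truth, "truth")
  check_same_dim(pred, truth, "masks")
  p <- pred == 1; t <- truth == 1
  tibble::tibble(
    tp = sum(p & t), fp = sum(p & !t),
    tn = sum(!p & !t), fn = sum(!p & t)
  )
}

metric_counts <- function(c) {
  if (is.data.frame(c)) c <- as.list(c[1, ])
  c
}

#' Overlap metrics from confusion counts
#'
#' `iou = tp/(tp+fp+fn)`, `dsc = 2 tp/(2 tp+fp+fn)`,
#' `acc = (tp+tn)/(tp+fp+tn+fn)`. When both masks are empty
#' (tp+fp+fn = 0) IoU and DSC are defined as 1 (perfect agreement, with a
#' warning); empty truth with non-empty prediction yields 0 through the
#' formulas directly.
#'
#' @param c Confusion counts (tibble row or named list).
#' @return Numeric scalar.
#' @export
iou <- function(c) {
  c <- metric_counts(c)
  denom <- c$tp + c$fp + c$fn
  if (denom == 0) {
    rlang::warn("both masks empty; IoU defined as 1")
    return(1.0)
  }
  c$tp / denom
}

#' @rdname iou
#' @export
dsc <- function(c) {
  c <- metric_counts(c)
  denom <- 2 * c$tp + c$fp + c$fn
  if (denom == 0) {
    rlang::warn("both masks empty; DSC defined as 1")
    return(1.0)
  }
  2 * c$tp / denom
}

#' @rdname iou
#' @export
acc <- function(c) {
  c <- metric_counts(c)
  (c$tp + c$tn) / (c$tp + c$fp + c$tn + c$fn)
}

#' All three segmentation metrics for one mask pair
#'
#' @param pred,truth 0/1 matrices.
#' @return One-row tibble with `iou`, `dsc`, `acc` and the raw counts.
#' @export
seg_metrics <- function(pred, truth) {
  cc <- confusion(pred, truth)
  dplyr::mutate(cc,
    iou = suppressWarnings(iou(cc)),
    dsc = suppressWarnings(dsc(cc)),
    acc = acc(cc)
  )
}

#' Evaluate a set of predicted masks against references (macro average)
#'
#' Per-image metrics are computed independently and averaged (macro
#' aggregation); the macro row carries `sample_id = "macro_average"`.
#'
#' @param preds,truths Equal-length lists of 0/1 matrices.
#' @param sample_ids Optional character ids.
#' @return Tibble of per-image rows plus a macro-average footer row.
#' @export
evaluate_masks <- function(preds, truths, sample_ids = NULL) {
  abort_if(length(preds) != length(truths), "pred/truth lists differ in length")
  ids <- sample_ids %||% sprintf("sample_%03d", seq_along(preds))
  per <- purrr::map2(preds, truths, seg_metrics)
  per <- dplyr::bind_rows(per)
  per <- dplyr::mutate(per, sample_id = ids, .before = 1)
  macro <- dplyr::summarise(per,
    sample_id = "macro_average",
    tp = NA_integer_, fp = NA_integer_, tn = NA_integer_, fn = NA_integer_,
    iou = mean(.data$iou), dsc = mean(.data$dsc), acc = mean(.data$acc))
  dplyr::bind_rows(per, macro)
}

#' Difference between two metric rows (e.g., two methods' IoU/DSC/Acc)
#'
#' @param a,b One-row tibbles/lists with `iou`, `dsc`, `acc` (on any common
#'   scale, e.g. percentage points).
#' @return One-row tibble of `a - b` per metric.
#' @export
metric_delta <- function(a, b) {
  a <- metric_counts(a); b <- metric_counts(b)
  tibble::tibble(iou = a$iou - b$iou, dsc = a$dsc - b$dsc,
                 acc = a$acc - b$acc)
}
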