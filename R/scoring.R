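# Min-max rescaling, the weighted composite melanin score, good/poor
# classification, and cohort-level agreement / correlation analysis.

#' Default composite-score weights
#'
#' `A_total` and `OD` are the primary indicators (weights 0.35 and 0.30);
#' `A_mean` mainly characterises distribution pattern (0.10) and
#' transmittance contributes 0.15. The weights deliberately sum to 0.90, so
#' with all rescaled metrics at 100 the maximal reachable score is 90.
#'
#' @return Named numeric vector over `a_total`, `a_mean`, `t`, `od`.
#' @export
default_score_weights <- function() {
  c(a_total = 0.35, a_mean = 0.10, t = 0.15, od = 0.30)
}

#' Min-max rescale a metric to a target range
#'
#' `x' = (x - x_min)/(x_max - x_min) * (b - a) + a` with target `(a, b) =
#' (0, 100)` by default. With fixed calibration bounds, out-of-range values
#' are clipped to the target range with a warning.
#'
#' @param x Numeric vector.
#' @param bounds `c(x_min, x_max)`; `NULL` uses the range of `x` (cohort
#'   bounds).
#' @param target `c(a, b)` target interval.
#' @param clip Clip values outside `bounds` (fixed-calibration mode).
#' @return Rescaled numeric vector.
#' @export
minmax_rescale <- function(x, bounds = NULL, target = c(0, 100),
                           clip = !is.null(bounds)) {
  fixed <- !is.null(bounds)
  if (!fixed) bounds <- range(x, na.rm = TRUE)
  abort_if(!(bounds[2] > bounds[1]),
           "degenerate bounds: x_max must exceed x_min")
  out <- (x - bounds[1]) / (bounds[2] - bounds[1]) *
    (target[2] - target[1]) + target[1]
  lo <- min(target); hi <- max(target)
  if (clip && any(out < lo | out > hi, na.rm = TRUE)) {
    if (fixed) rlang::warn("values outside calibration bounds were clipped")
    out <- pmin(pmax(out, lo), hi)
  }
  out
}

#' Weighted composite melanin score
#'
#' `score = w_Atotal A'_total + w_Amean A'_mean + w_T T' + w_OD OD'` over
#' rescaled metrics in \[0,100\]. Higher scores indicate more severe melanin
#' deposition; with the default weights the reachable range is \[0, 90\].
#'
#' @param normalized Numeric vector/list of the four rescaled metrics in the
#'   order (A'_total, A'_mean, T', OD'), or a named vector matching the
#'   weight names.
#' @param weights Named weights (default [default_score_weights()]).
#' @return Scalar score.
#' @export
composite_score <- function(normalized, weights = default_score_weights()) {
  normalized <- unlist(normalized)
  abort_if(length(normalized) != length(weights),
           "normalized metrics and weights differ in length")
  abort_if(any(weights < 0), "weights must be non-negative")
  if (!is.null(names(normalized)) && all(names(weights) %in% names(normalized))) {
    normalized <- normalized[names(weights)]
  }
  sum(weights * normalized)
}

#' Classify a composite score as good or poor
#'
#' Higher scores mean more severe melanin deposition, so scores at or above
#' the cutoff are `"poor"` (boundary inclusive).
#'
#' @param score Numeric vector of scores.
#' @param cutoff Decision threshold (default 45, the midpoint of the
#'   reachable \[0,90\] range).
#' @return Character vector of `"good"`/`"poor"`.
#' @export
classify <- function(score, cutoff = 45) {
  abort_if(any(!is.finite(score)), "scores must be finite")
  ifelse(score >= cutoff, "poor", "good")
}

#' Score a cohort of quantified samples
#'
#' Takes the metrics tibble from [quantify_cohort()] (columns `a_total_px`,
#' `a_mean_px`, `transmittance_pct`, `optical_density`), min-max rescales
#' each metric to \[0,100\], combines them with the composite weights and
#' classifies each sample at `cutoff`.
#'
#' Raw transmittance falls as pigment deposition grows, while the score is
#' defined so that higher means heavier deposition; by default the
#' transmittance axis is therefore inverted before rescaling
#' (`invert_t = TRUE`). `invert_t = FALSE` applies the literal formula.
#'
#' @param metrics Tibble of per-sample metrics.
#' @param weights Named weights (default [default_score_weights()]).
#' @param cutoff Classification threshold (default 45).
#' @param bounds Optional named list of fixed calibration bounds per metric
#'   (`a_total`, `a_mean`, `t`, `od`), each `c(min, max)`; `NULL` derives
#'   bounds from the cohort.
#' @param invert_t Invert the transmittance axis before rescaling.
#' @return The input tibble plus `a_total_norm`, `a_mean_norm`, `t_norm`,
#'   `od_norm`, `score`, `classification`, `cutoff_used`.
#' @export
score_samples <- function(metrics, weights = default_score_weights(),
                          cutoff = 45, bounds = NULL, invert_t = TRUE) {
  need <- c("a_total_px", "a_mean_px", "transmittance_pct", "optical_density")
  abort_if(!all(need %in% names(metrics)),
           paste0("metrics must contain: ", paste(need, collapse = ", ")))
  t_raw <- if (invert_t) -metrics$transmittance_pct else metrics$transmittance_pct
  t_bounds <- bounds$t
  if (!is.null(t_bounds) && invert_t) t_bounds <- sort(-t_bounds)
  out <- dplyr::mutate(metrics,
    a_total_norm = minmax_rescale(.data$a_total_px, bounds$a_total),
    a_mean_norm = minmax_rescale(.data$a_mean_px, bounds$a_mean),
    t_norm = minmax_rescale(t_raw, t_bounds),
    od_norm = minmax_rescale(.data$optical_density, bounds$od)
  )
  # samples without any melanin patch have undefined T/OD; they sit at the
  # least-severe end of both optical axes, so their rescaled value is 0
  no_patch <- is.na(out$t_norm) | is.na(out$od_norm)
  if (any(no_patch)) {
    rlang::warn("samples without patches score 0 on the optical metrics")
    out$t_norm[is.na(out$t_norm)] <- 0
    out$od_norm[is.na(out$od_norm)] <- 0
  }
  norm <- cbind(out$a_total_norm, out$a_mean_norm, out$t_norm, out$od_norm)
  out$score <- as.numeric(norm %*% weights)
  out$classification <- classify(out$score, cutoff)
  out$cutoff_used <- cutoff
  out
}

#' Cohort-level agreement and correlation analysis
#'
#' Cross-tabulates predicted vs. manual good/poor calls, reports the overall
#' agreement percentage, and computes the Pearson correlation matrix among
#' the raw metrics and the manual label (coded good = 0, poor = 1, so
#' positive r means "metric rises with deposition severity"). Constant
#' columns yield `NA` correlations.
#'
#' @param scores Tibble from [score_samples()] (needs `classification`;
#'   metric columns are used for the correlation matrix when present), or a
#'   character vector of predicted labels.
#' @param manual_labels Character vector of manual `"good"`/`"poor"` calls
#'   (`"bad"` is accepted as a synonym for `"poor"`).
#' @return A `melachip_cohort_report`: list with `confusion` (2x2 table,
#'   predicted x manual), `agreement_pct`, `pearson` (correlation matrix or
#'   `NULL`), `n`.
#' @export
cohort_analysis <- function(scores, manual_labels) {
  canon <- function(x) ifelse(x %in% c("bad", "poor"), "poor", "good")
  if (is.character(scores)) {
    pred <- canon(scores)
    metrics <- NULL
  } else {
    abort_if(!"classification" %in% names(scores),
             "scores must carry a classification column")
    pred <- canon(scores$classification)
    metrics <- scores
  }
  manual <- canon(manual_labels)
  abort_if(length(pred) != length(manual),
           "predictions and manual labels differ in length")
  lv <- c("good", "poor")
  conf <- table(factor(pred, lv), factor(manual, lv), dnn = c("predicted", "manual"))
  agreement <- 100 * sum(diag(conf)) / sum(conf)
  pearson <- NULL
  if (!is.null(metrics) && length(manual) >= 3) {
    cols <- c(a_total = "a_total_px", od = "optical_density",
              t = "transmittance_pct", a_mean = "a_mean_px")
    have <- cols[cols %in% names(metrics)]
    if (length(have) > 0) {
      m <- as.matrix(metrics[, have, drop = FALSE])
      colnames(m) <- names(have)
      m <- cbind(m, label = as.numeric(manual == "poor"))
      sds <- apply(m, 2, sd)
      pearson <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
      pearson[sds == 0, ] <- NA_real_
      pearson[, sds == 0] <- NA_real_
      diag(pearson) <- 1
    }
  }
  structure(list(confusion = conf, agreement_pct = agreement,
                 pearson = pearson, n = length(manual)),
            class = "melachip_cohort_report")
}

#' @export
print.melachip_cohort_report <- function(x, ...) {
  cat(sprintf("<melachip_cohort_report> n = %d, overall agreement %.1f%%\n",
              x$n, x$agreement_pct))
  print(x$confusion)
  invisible(x)
}
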