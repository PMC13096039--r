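# broom-style accessors for fitted models and cohort reports.

#' Tidy a trained model's loss curves
#'
#' @param x A `melachip_model` from [train()].
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`, `lr`.
#' @export
tidy.melachip_model <- function(x, ...) {
  x$curves %||% tibble::tibble(epoch = integer(), train_loss = numeric(),
                               val_loss = numeric(), lr = numeric())
}

#' One-row summary of a trained model
#'
#' @param x A `melachip_model`.
#' @param ... Unused.
#' @return Tibble with parameter count, epochs, best epoch and losses.
#' @export
glance.melachip_model <- function(x, ...) {
  cv <- tidy(x)
  tibble::tibble(
    n_parameters = sum(vapply(x$params, length, integer(1))),
    epochs_completed = x$epochs_completed,
    best_epoch = x$best_epoch %||% NA_integer_,
    final_train_loss = if (nrow(cv)) cv$train_loss[nrow(cv)] else NA_real_,
    best_val_loss = if (nrow(cv)) min(cv$val_loss) else NA_real_,
    final_lr = if (nrow(cv)) cv$lr[nrow(cv)] else NA_real_
  )
}

#' Tidy a cohort report's correlation structure
#'
#' @param x A `melachip_cohort_report` from [cohort_analysis()].
#' @param ... Unused.
#' @return Long tibble of pairwise Pearson correlations (or empty when no
#'   metric columns were available).
#' @export
tidy.melachip_cohort_report <- function(x, ...) {
  if (is.null(x$pearson)) {
    return(tibble::tibble(var1 = character(), var2 = character(),
                          r = numeric()))
  }
  m <- x$pearson
  tibble::tibble(
    var1 = rep(rownames(m), times = ncol(m)),
    var2 = rep(colnames(m), each = nrow(m)),
    r = as.vector(m)
  )
}

#' One-row summary of a cohort report
#'
#' @param x A `melachip_cohort_report`.
#' @param ... Unused.
#' @return Tibble with n, agreement percentage and confusion cells.
#' @export
glance.melachip_cohort_report <- function(x, ...) {
  cf <- x$confusion
  tibble::tibble(
    n = x$n, agreement_pct = x$agreement_pct,
    good_correct = cf["good", "good"], good_miss = cf["poor", "good"],
    poor_correct = cf["poor", "poor"], poor_miss = cf["good", "poor"]
  )
}
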