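# ggplot2 displays for samples, training curves, scores and cohort reports.

#' Plot a synthetic or loaded sample (image with mask outline overlay)
#'
#' @param object A `melachip_sample`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.melachip_sample <- function(object, ...) {
  img <- object$image; mask <- object$mask
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$intensity <- img[cbind(df$row, df$col)]
  df$melanin <- mask[cbind(df$row, df$col)] == 1
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$melanin),
                        colour = "red", size = 0.1, alpha = 0.15) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("sample (", object$label, ")"),
                  x = NULL, y = NULL, fill = "I") +
    ggplot2::theme_minimal()
}

#' Plot training and validation loss curves
#'
#' @param object A trained `melachip_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.melachip_model <- function(object, ...) {
  cv <- tidy(object)
  long <- tidyr::pivot_longer(cv, c("train_loss", "val_loss"),
                              names_to = "set", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "MEM-ViT training", x = "epoch",
                  y = "composite loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cohort scores coloured by classification
#'
#' @param scores Tibble from [score_samples()].
#' @return A ggplot object.
#' @export
plot_scores <- function(scores) {
  df <- dplyr::mutate(scores, rank = rank(.data$score, ties.method = "first"))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$score,
                                   colour = .data$classification)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = df$cutoff_used[1], linetype = 2) +
    ggplot2::labs(x = "sample (ranked)", y = "composite score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Correlation heatmap of metrics vs. labels for a cohort report
#'
#' @param object A `melachip_cohort_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.melachip_cohort_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$var1, .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}
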