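#' Plot posterior densities of a decision-noise fit
#'
#' @param object A `noise_fit`.
#' @param ... Unused.
#' @return A ggplot with one density panel per parameter.
#' @export
autoplot.noise_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$samples, c("f", "p_guess"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density",
                  title = "Decision-noise parameters") +
    ggplot2::theme_minimal()
}

#' Plot a transfer-testing matrix
#'
#' @param object A [transfer_matrix()] tibble.
#' @param ... Unused.
#' @return A ggplot heat map of MSE x 100 per (model, split).
#' @export
autoplot.transfer_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$split, y = .data$model,
                                       fill = .data$mse100)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mse100)),
                       colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "evaluated on", y = "model",
                  fill = "MSE × 100") +
    ggplot2::theme_minimal()
}

#' Bar plot of single-feature R-squared values
#'
#' @param r2_table Output of [feature_r2_table()].
#' @return A ggplot bar chart with confidence-interval error bars, coloured
#'   by feature group.
#' @export
plot_feature_r2 <- function(r2_table) {
  ggplot2::ggplot(r2_table,
                  ggplot2::aes(x = stats::reorder(.data$feature,
                                                  .data$r_squared),
                               y = .data$r_squared, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(R^2), fill = "group") +
    ggplot2::theme_minimal()
}
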