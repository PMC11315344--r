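#' Plot the per-channel color-gradation histograms of an image
#'
#' Line plot of the R, G, B and Y gradation histograms after pixel filtering;
#' the severity signature shows as a rightward shift, flattening and skewing
#' of the curves.
#'
#' @param image A [canopy_image()].
#' @param ... Passed to [filter_canopy_pixels()].
#' @return A ggplot object.
#' @export
plot_channel_histograms <- function(image, ...) {
  hist <- channel_histograms(filter_canopy_pixels(image, ...))
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$value, y = .data$count,
                                     color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(R = "#c0392b", G = "#27ae60",
                                           B = "#2980b9", Y = "#7f8c8d")) +
    ggplot2::labs(x = "color gradation value", y = "pixel count",
                  color = "channel") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(unclass(object)))
  df <- tidyr::pivot_longer(
    dplyr::mutate(df, reference = rownames(object)),
    -"reference", names_to = "predicted", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$reference,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2980b9") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted grade", y = "reference grade") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.factor_model <- function(object, ...) {
  if (is.null(object$eigenvalues)) {
    abort("this factor model carries no eigenvalues to plot",
          class = "frostgrade_error_arg")
  }
  df <- tibble::tibble(factor = seq_along(object$eigenvalues),
                       eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "composite factor", y = "eigenvalue") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.key_parameter_scores <- function(object, k = 6, ...) {
  keys <- select_key_parameters(object, k = min(k, nrow(object)))
  df <- dplyr::mutate(tibble::as_tibble(object),
                      selected = .data$feature %in% keys)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$abs_fsc),
    y = .data$abs_fsc, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "|FSC| (combined score coefficient)",
                  fill = "key parameter") +
    ggplot2::theme_minimal()
}
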