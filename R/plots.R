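# Diagnostic figures: error vector field, consistency distributions,
# PCA loadings.

#' Plot the mean error vector field over the hand
#'
#' Arrows from each actual landmark position to the across-subject mean
#' perceived position, over the actual hand layout.
#'
#' @param errors An error table from [error_table()].
#' @param landmarks Actual landmark coordinates.
#' @return A ggplot object.
#' @export
plot_error_field <- function(errors, landmarks) {
  ph <- perceived_hand(errors, landmarks) |>
    dplyr::group_by(landmark) |>
    dplyr::summarise(
      actual_x = mean(actual_x), actual_y = mean(actual_y),
      perceived_x_cm = mean(perceived_x_cm), perceived_y_cm = mean(perceived_y_cm),
      .groups = "drop"
    ) |>
    add_landmark_factors()
  ggplot2::ggplot(ph, ggplot2::aes(x = actual_x, y = actual_y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = perceived_x_cm, yend = perceived_y_cm, colour = type),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "medio-lateral (cm)", y = "proximo-distal (cm)",
      title = "Mean localization error vectors", colour = "landmark type"
    ) +
    ggplot2::theme_minimal()
}

#' Plot angle-consistency distributions by landmark type
#'
#' @param records Consistency records (per-landmark scope).
#' @return A ggplot object.
#' @export
plot_consistency <- function(records) {
  d <- records |>
    dplyr::filter(!is.na(type))
  ggplot2::ggplot(d, ggplot2::aes(x = type, y = itpc, fill = type)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "angle consistency (ITPC)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot PC1 loadings of an error PCA
#'
#' @param object An `error_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_pca <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::filter(component == 1) |>
    add_landmark_factors() |>
    dplyr::mutate(landmark = factor(landmark, levels = hand_landmark_labels()))
  ggplot2::ggplot(d, ggplot2::aes(x = landmark, y = loading, fill = type)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      title = sprintf(
        "PC1 loadings (%s errors, %.1f%% variance)",
        object$axis, 100 * object$variance_explained[1]
      ),
      x = NULL, y = "loading"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
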