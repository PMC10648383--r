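# ggplot2 views of the main result types.

#' Plot superimposed landmarks and the consensus shape
#'
#' @param object A `wing_gpa` fit.
#' @param ... Unused.
#' @return A ggplot: per-specimen superimposed landmark scatter with the
#'   consensus shape overlaid.
#' @exportS3Method ggplot2::autoplot
autoplot.wing_gpa <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(dplyr::matches("^[xy][0-9]+$"),
                        names_to = c(".value", "landmark"),
                        names_pattern = "([xy])([0-9]+)") |>
    dplyr::mutate(landmark = as.integer(.data$landmark))
  cons <- tibble::tibble(landmark = seq_len(object$k),
                         x = object$consensus[, 1L], y = object$consensus[, 2L])
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "grey40") +
    ggplot2::geom_point(data = cons, colour = "black", size = 2) +
    ggplot2::geom_text(data = cons, ggplot2::aes(label = .data$landmark),
                       vjust = -0.9, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Superimposed landmarks and consensus shape") +
    ggplot2::theme_minimal()
}

#' Scatter plot of shape PCA scores
#'
#' @param object A `wing_pca` result.
#' @param colour Bare column name of the metadata variable used for colour
#'   (default `species`).
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 with percentage-of-variance axis labels.
#' @exportS3Method ggplot2::autoplot
autoplot.wing_pca <- function(object, colour = species, ...) {
  scores <- tidy(object)
  evr <- object$explained_variance_ratio
  ggplot2::ggplot(scores, ggplot2::aes(.data$PC1, .data$PC2,
                                       colour = {{ colour }})) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::stat_ellipse(level = 0.95, linewidth = 0.4) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * evr[1L]),
                  y = sprintf("PC2 (%.1f%%)", 100 * evr[2L])) +
    ggplot2::theme_minimal()
}

#' Plot per-landmark mean-shape displacements between two groups
#'
#' Arrows from one group's mean landmark positions to the other's, magnified
#' for visibility.
#'
#' @param object A `landmark_diff` result.
#' @param magnify Displacement magnification factor for the arrows.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.landmark_diff <- function(object, magnify = 10, ...) {
  m2 <- object$mean_shapes[[2L]]
  tab <- tidy(object)
  df <- tibble::tibble(landmark = tab$landmark,
                       x = m2[, 1L], y = m2[, 2L],
                       xend = m2[, 1L] + magnify * tab$dx,
                       yend = m2[, 2L] + magnify * tab$dy,
                       top = tab$rank == 1L)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$xend, yend = .data$yend,
                                       colour = .data$top),
                          arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "cm")),
                          show.legend = FALSE) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_text(ggplot2::aes(label = .data$landmark), vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Mean-shape displacement (x%g): %s vs %s",
                                  magnify, object$groups[1L], object$groups[2L])) +
    ggplot2::theme_minimal()
}
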