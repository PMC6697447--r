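#' Plot a dissimilarity matrix as a heat map
#'
#' Darker cells indicate more similar (likely adjacent) sections; sentinel
#' (no-match) pairs are blank. With `order`, rows and columns are permuted
#' to a recovered or ground-truth order, which turns a successful
#' reconstruction into a dark band along the diagonal.
#'
#' @param object A `dissimilarity_matrix`.
#' @param order Optional `section_order` (or id vector) to permute by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dissimilarity_matrix <- function(object, order = NULL, ...) {
  ids <- matrix_ids(object)
  lv <- if (is.null(order)) ids else order_ids(order)
  df <- tidy.dissimilarity_matrix(object)
  df <- dplyr::bind_rows(
    df,
    dplyr::rename(df, section_a = "section_b", section_b = "section_a"),
    tibble(section_a = ids, section_b = ids, dissimilarity = 0,
           matched = TRUE)
  )
  df$dissimilarity[!df$matched] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$section_a, levels = lv),
    y = factor(.data$section_b, levels = rev(lv)),
    fill = .data$dissimilarity
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "grey90",
                                 na.value = "white") +
    ggplot2::labs(x = "section", y = "section", fill = "dissimilarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot the link-cost frequency histogram
#'
#' The distribution of per-link costs: a perfect reordering is a single bar
#' at 0; stray links at higher costs localize ordering mistakes.
#'
#' @param object A `link_cost_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.link_cost_report <- function(object, ...) {
  df <- tibble(cost = object$costs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cost)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "link cost", y = "links") +
    ggplot2::theme_minimal()
}

#' Plot detected beads over a section field
#'
#' @param object A bead tibble (`x`, `y`, `diameter`, `section_id`).
#' @param sections Optional subset of section ids to show.
#' @param ... Unused.
#' @return A ggplot object, one facet per section.
#' @export
plot_beads <- function(object, sections = NULL, ...) {
  if (!is.null(sections)) {
    object <- dplyr::filter(object, .data$section_id %in% sections)
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       size = .data$diameter)) +
    ggplot2::geom_point(alpha = 0.6, colour = "darkgreen") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_size_identity() +
    ggplot2::facet_wrap(ggplot2::vars(.data$section_id)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
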