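#' Plot the cell-cycle plane
#'
#' DC1-DC2 scatter colored by phase, with the division point on the
#' positive DC1 axis and phase-boundary spokes.
#'
#' @param object a `cc_cycle_coordinates` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cc_cycle_coordinates
#' @export
autoplot.cc_cycle_coordinates <- function(object, ...) {
  cells <- object$cells
  rmax <- max(cells$radius)
  spokes <- dplyr::mutate(object$boundaries,
                          x = rmax * cos(.data$angle),
                          y = rmax * sin(.data$angle))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$dc1, y = .data$dc2)) +
    ggplot2::geom_segment(data = spokes,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          linetype = "dashed", color = "grey60",
                          inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(color = .data$phase), size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "DC1", y = "DC2", color = "phase",
                  title = "Cell cycle in the DC1-DC2 plane") +
    ggplot2::theme_minimal()
}

#' Plot per-component cluster and marker scores
#'
#' @param scores named list with `cluster` and `marker` numeric vectors
#'   (per component) and optionally `baseline` (marker baseline).
#' @param n_components leading components to show (default 10).
#' @return A ggplot object.
#' @export
plot_component_scores <- function(scores, n_components = 10) {
  k <- min(n_components, length(scores$cluster))
  df <- tibble::tibble(
    component = rep(seq_len(k), 2),
    score = c(scores$cluster[seq_len(k)], scores$marker[seq_len(k)]),
    type = rep(c("cluster score", "marker score"), each = k)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$component),
                                        y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~type, scales = "free_y") +
    ggplot2::labs(x = "component", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(scores$baseline)) {
    p <- p + ggplot2::geom_hline(
      data = tibble::tibble(type = "marker score", y = scores$baseline),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed")
  }
  p
}

#' Plot a variance decomposition
#'
#' Stacked per-component fractions of directly explained (`cc`), implied
#' (cross-covariance), and unexplained variance.
#'
#' @param decomposition tibble from [variance_decomposition()].
#' @return A ggplot object.
#' @export
plot_variance_decomposition <- function(decomposition) {
  long <- tidyr::pivot_longer(
    dplyr::select(decomposition, "component", "cc", "implied", "unexplained"),
    cols = c("cc", "implied", "unexplained"),
    names_to = "source", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$component),
                                     y = .data$fraction,
                                     fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "component", y = "fraction of variance") +
    ggplot2::theme_minimal()
}

#' Plot a smoothed displacement field
#'
#' @param object a `cc_field` tibble from [grid_smooth()] or
#'   [cylinder_side_field()].
#' @param arrow_scale multiplier on arrow lengths for display (default 1).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cc_field
#' @export
autoplot.cc_field <- function(object, arrow_scale = 1, ...) {
  shown <- dplyr::filter(object, .data$shown)
  ggplot2::ggplot(shown, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + arrow_scale * .data$dx,
                                       yend = .data$y + arrow_scale * .data$dy),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
                          color = "grey30") +
    ggplot2::theme_minimal()
}

#' Plot binned gene time courses over pseudotime
#'
#' @param courses genes x bins matrix of binned means (rows named by gene),
#'   or the scaled matrix attached to [onset_times()] output.
#' @return A ggplot object with one line per gene.
#' @export
plot_time_courses <- function(courses) {
  df <- tibble::as_tibble(courses, rownames = "gene")
  long <- tidyr::pivot_longer(df, cols = -"gene", names_to = "bin",
                              values_to = "value")
  long$bin <- as.integer(gsub("\\D", "", long$bin))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$value,
                                     color = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pseudotime bin", y = "expression") +
    ggplot2::theme_minimal()
}

#' Plot the transition-index profile
#'
#' @param object a `cc_transition_profile` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cc_transition_profile
#' @export
autoplot.cc_transition_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$ic)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "angular bin", y = "transition index") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
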