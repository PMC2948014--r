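#' Plot a magnitude-weighted angle distribution
#'
#' Line plot of the pdf over `[0, 180]` degrees with the CAI window
#' shaded, mirroring the conventional presentation of gradient-edge angle
#' histograms.
#'
#' @param object an `angle_distribution`.
#' @param lo_deg,hi_deg shaded CAI window (degrees).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.angle_distribution <- function(object, lo_deg = 60, hi_deg = 120, ...) {
  df <- tidy(object)
  cai <- collagen_alignment_index(object, lo_deg, hi_deg)$cai
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center_deg, y = .data$pdf)) +
    ggplot2::annotate("rect", xmin = lo_deg, xmax = hi_deg,
                      ymin = 0, ymax = Inf, alpha = 0.15, fill = "red") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "gradient-edge angle (degrees)", y = "probability density",
      title = sprintf("CAI = %.3f over [%g, %g]", cai, lo_deg, hi_deg)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cell-graph as a 2D projection
#'
#' Projects nodes onto the (x, y) plane; edges are drawn as segments,
#' coloured by weight when the graph carries one.
#'
#' @param object a `cell_graph`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cell_graph <- function(object, ...) {
  nodes <- object$nodes
  p <- ggplot2::ggplot()
  if (nrow(object$edges)) {
    e <- object$edges
    seg <- tibble::tibble(
      x = nodes$x_um[match(e$u, nodes$id)],
      y = nodes$y_um[match(e$u, nodes$id)],
      xend = nodes$x_um[match(e$v, nodes$id)],
      yend = nodes$y_um[match(e$v, nodes$id)],
      weight = if ("weight" %in% names(e)) e$weight else NA_real_
    )
    p <- p + if (all(is.na(seg$weight))) {
      ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
        colour = "grey40")
    } else {
      ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, colour = .data$weight))
    }
  }
  p +
    ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x_um, y = .data$y_um), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Plot metric trajectories of a time course
#'
#' @param metrics tibble with columns `timepoint` and one or more metric
#'   columns (e.g. `cai`, `gdl`).
#' @return A ggplot object, one facet per metric.
#' @export
plot_timecourse_metrics <- function(metrics) {
  stopifnot("timepoint" %in% names(metrics))
  long <- tidyr::pivot_longer(metrics, -"timepoint",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time point", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
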