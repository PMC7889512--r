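#' Plot a vein layout
#'
#' Draws the edge network coloured by vein order, line width decreasing with
#' order.
#'
#' @param object A `vein_layout`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vein_layout <- function(object, ...) {
  e <- tidy(object)
  e$order <- factor(e$order)
  ggplot2::ggplot(e) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x1, y = .data$z1, xend = .data$x2, yend = .data$z2,
                   colour = .data$order,
                   linewidth = .data$order),
      lineend = "round"
    ) +
    ggplot2::scale_linewidth_manual(
      values = c(`1` = 1.6, `2` = 1.0, `3` = 0.5, `4` = 0.25, `5` = 0.25),
      guide = "none"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "z (m)", colour = "vein order",
                  title = sprintf("%s leaf, theta = %.2f deg",
                                  object$shape$variant, object$theta)) +
    ggplot2::theme_minimal()
}

#' Plot a solved field as a leaf map
#'
#' @param object A [solve_steady()] result.
#' @param field `"p_xyl"`, `"p_ph"`, `"C"` or `"p_diff"` (the xylem-minus-
#'   phloem total-pressure circulation map).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.leaf_steady <- function(object, field = "p_xyl", ...) {
  nd <- if (identical(field, "p_diff")) {
    pressure_difference_map(object)
  } else {
    object$nodes
  }
  nd <- nd[nd$node != object$petiole, ]
  h <- object$spacing
  lab <- c(p_xyl = "xylem pressure (MPa)", p_ph = "phloem pressure (MPa)",
           C = "sucrose (mol m^-3)", p_diff = "p_xyl - (p_ph - RTC) (MPa)")[field]
  ggplot2::ggplot(nd, ggplot2::aes(x = .data$x, y = .data$z, fill = .data[[field]])) +
    ggplot2::geom_tile(width = h, height = h) +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "z (m)",
                  title = sprintf("%s leaf, theta = %.2f deg",
                                  object$meta$variant, object$meta$theta)) +
    ggplot2::theme_minimal()
}

#' Plot angle-response curves
#'
#' @param object A [sweep_vein_angle()] result.
#' @param field Sweep column to plot.
#' @param ... Unused.
#' @return A ggplot of the area-average index versus vein angle.
#' @export
autoplot.vein_sweep <- function(object, field = "avg_p_xyl", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta, y = .data[[field]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "second-order vein angle (deg from perpendicular)", y = field,
      title = sprintf("%s leaf", attr(object, "variant") %||% "")
    ) +
    ggplot2::theme_minimal()
}
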