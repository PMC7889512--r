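#' Tidy a solved leaf state
#'
#' @param x A [solve_steady()] result.
#' @param ... Unused.
#' @return A tibble with one row per node: lattice indices, position, area,
#'   `p_xyl`, `p_ph`, `C` and a `petiole` flag.
#' @export
tidy.leaf_steady <- function(x, ...) {
  nd <- x$nodes
  nd$petiole <- nd$node == x$petiole
  nd
}

#' One-row summary of a solved leaf state
#'
#' @param x A [solve_steady()] result.
#' @param ... Unused.
#' @return A one-row tibble: leaf variant, vein angle, node count, the three
#'   area-average indices, iteration count, final scaled residual and the
#'   sucrose conservation gap of the convection scheme in use.
#' @export
glance.leaf_steady <- function(x, ...) {
  d <- x$diagnostics
  tibble(
    variant = x$meta$variant,
    theta = x$meta$theta,
    n_nodes = x$meta$n_inside,
    avg_p_xyl = area_average(x, "p_xyl"),
    avg_p_ph = area_average(x, "p_ph"),
    avg_C = area_average(x, "C"),
    iterations = d$iterations,
    residual = d$residual,
    sucrose_gap = d$sucrose_conservation_gap
  )
}

#' Tidy a vein layout
#'
#' @param x A `vein_layout`.
#' @param ... Unused.
#' @return The edge tibble joined with endpoint coordinates.
#' @export
tidy.vein_layout <- function(x, ...) {
  nd <- x$nodes
  e <- x$edges
  e$x1 <- nd$x[match(e$from, nd$node)]
  e$z1 <- nd$z[match(e$from, nd$node)]
  e$x2 <- nd$x[match(e$to, nd$node)]
  e$z2 <- nd$z[match(e$to, nd$node)]
  e
}
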