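#' Construct a parameterised leaf outline
#'
#' Builds one of three lanceolate leaf outlines that share the same blade area
#' (73.35 cm^2) but differ in length-to-width proportion. The half-width
#' profile is the smooth family \eqn{w(z) = (W/2)\,\sin(\pi z/L)^q}, with the
#' shape exponent \eqn{q} solved numerically so that the outline area
#' \eqn{\int_0^L 2 w(z)\,dz} equals the target area exactly.
#'
#' @param variant One of `"reference"` (L = 16.00 cm, W = 6.47 cm),
#'   `"wide"` (L = 12.8 cm, W = 8.09 cm) or `"narrow"` (L = 19.2 cm,
#'   W = 5.39 cm).
#'
#' @return An object of class `leaf_shape`: a list with fields `variant`,
#'   `length` (m), `width` (m), `area` (m^2), `exponent` (the fitted q) and
#'   `half_width`, a vectorised function of longitudinal position z (m)
#'   returning the half-width (m).
#'
#' @examples
#' sh <- make_leaf_shape("reference")
#' sh$half_width(sh$length / 2)  # half the maximum width at mid-blade
#' @export
make_leaf_shape <- function(variant = c("reference", "wide", "narrow")) {
  variant <- match.arg(variant)
  dims <- switch(variant,
    reference = c(L = 0.160, W = 0.0647),
    wide      = c(L = 0.128, W = 0.0809),
    narrow    = c(L = 0.192, W = 0.0539)
  )
  area <- 73.35e-4
  L <- unname(dims["L"])
  W <- unname(dims["W"])

  # area(q) = W * L/pi * int_0^pi sin(t)^q dt; the integral has the closed
  # form sqrt(pi) * gamma((q+1)/2) / gamma(q/2 + 1).
  ratio <- area / (L * W) # fraction of the bounding box filled by the blade
  f <- function(q) sqrt(pi) * gamma((q + 1) / 2) / gamma(q / 2 + 1) / pi - ratio
  q <- uniroot(f, c(1e-3, 10), tol = 1e-13)$root

  half_width <- function(z) {
    s <- sin(pi * pmin(pmax(z, 0), L) / L)
    (W / 2) * s^q
  }

  structure(
    list(
      variant = variant, length = L, width = W, area = area,
      exponent = q, half_width = half_width
    ),
    class = "leaf_shape"
  )
}

#' @export
print.leaf_shape <- function(x, ...) {
  cat(sprintf(
    "<leaf_shape '%s'>  L = %.1f cm, W = %.2f cm, area = %.2f cm^2, q = %.4f\n",
    x$variant, 100 * x$length, 100 * x$width, 1e4 * x$area, x$exponent
  ))
  invisible(x)
}

#' Build the node lattice for a leaf shape
#'
#' Places nodes on a square lattice of the given spacing, keeps those inside
#' the outline, and attaches an external petiole node at the leaf base on the
#' symmetry axis. The petiole is linked to the first internal main-vein node
#' by a conduit of fixed length 5 mm. Per-node areas are computed by clipping
#' each lattice cell against the outline (marginal cells absorb the sliver of
#' blade beyond the outermost node of their row), so the nodal areas sum to
#' the blade area.
#'
#' @param shape A [make_leaf_shape()] object.
#' @param spacing Lattice spacing in metres (default 0.002).
#'
#' @return An object of class `leaf_grid`: list with `nodes` (tibble: `node`,
#'   `i` longitudinal index, `j` lateral index, `x`, `z`, `area`), `petiole`
#'   (node id of the external petiole node), `first_node` (id of the internal
#'   main-vein node adjacent to the petiole), `spacing`, `ni`, `jmax`,
#'   `id_of(i, j)` lookup and `inside(i, j)` predicate, and the `shape`.
#' @export
build_grid <- function(shape, spacing = 0.002) {
  stopifnot(inherits(shape, "leaf_shape"), is.numeric(spacing), spacing > 0)
  if (spacing >= shape$width / 4) {
    abort(sprintf(
      "spacing %.4g m is too coarse for leaf width %.4g m (need spacing < W/4)",
      spacing, shape$width
    ))
  }
  h <- spacing
  L <- shape$length
  ni <- floor((L - 1e-12) / h) # rows i = 1..ni at z = i*h < L
  jmax <- floor(shape$width / 2 / h) + 1L

  grid_ij <- expand.grid(i = seq_len(ni), j = seq.int(-jmax, jmax))
  w_row <- shape$half_width(grid_ij$i * h)
  keep <- abs(grid_ij$j) * h <= w_row + 1e-12
  nodes <- tibble(
    i = as.integer(grid_ij$i[keep]), j = as.integer(grid_ij$j[keep])
  )
  nodes <- nodes[order(nodes$i, nodes$j), ]
  nodes$node <- seq_len(nrow(nodes))
  nodes$x <- nodes$j * h
  nodes$z <- nodes$i * h

  nodes$area <- .nodal_areas(nodes, shape, h, ni)

  petiole <- nrow(nodes) + 1L
  first_node <- nodes$node[nodes$i == 1L & nodes$j == 0L]
  if (length(first_node) != 1L) {
    abort("lattice does not contain the first main-vein node (i = 1, j = 0)")
  }

  id <- matrix(NA_integer_, nrow = ni, ncol = 2L * jmax + 1L)
  id[cbind(nodes$i, nodes$j + jmax + 1L)] <- nodes$node
  id_of <- function(i, j) {
    ok <- i >= 1L & i <= ni & abs(j) <= jmax
    out <- rep(NA_integer_, length(i))
    out[ok] <- id[cbind(i[ok], j[ok] + jmax + 1L)]
    out
  }
  inside <- function(i, j) !is.na(id_of(i, j))

  nodes <- nodes[, c("node", "i", "j", "x", "z", "area")]
  structure(
    list(
      nodes = as_tibble(nodes), petiole = petiole, first_node = first_node,
      spacing = h, ni = ni, jmax = jmax, id_of = id_of, inside = inside,
      petiole_length = 0.005, shape = shape
    ),
    class = "leaf_grid"
  )
}

# Clip lattice cells to the outline, row band by row band. Row bands partition
# [0, L] (the first and last bands are extended to the base/apex), and within
# a row the outermost node cells are extended to the margin, so the areas sum
# to the blade area up to quadrature error.
.nodal_areas <- function(nodes, shape, h, ni) {
  areas <- numeric(nrow(nodes))
  # 15-point Simpson weights over the band
  np <- 15L
  wts <- c(1, rep(c(4, 2), (np - 3) / 2), 4, 1)
  for (ii in seq_len(ni)) {
    sel <- which(nodes$i == ii)
    if (!length(sel)) next
    z <- ii * h
    zlo <- if (ii == 1L) 0 else z - h / 2
    zhi <- if (ii == ni) shape$length else z + h / 2
    zq <- seq(zlo, zhi, length.out = np)
    wq <- shape$half_width(zq)
    dz <- (zhi - zlo) / (np - 1)
    xs <- nodes$j[sel] * h
    lo <- xs - h / 2
    hi <- xs + h / 2
    lo[which.min(xs)] <- -Inf
    hi[which.max(xs)] <- Inf
    for (k in seq_along(sel)) {
      ov <- pmax(0, pmin(hi[k], wq) - pmax(lo[k], -wq))
      areas[sel[k]] <- sum(wts * ov) * dz / 3
    }
  }
  areas
}

#' @export
print.leaf_grid <- function(x, ...) {
  cat(sprintf(
    "<leaf_grid '%s'>  spacing %.1f mm, %d inside nodes (+ petiole), total area %.2f cm^2\n",
    x$shape$variant, 1000 * x$spacing, nrow(x$nodes), 1e4 * sum(x$nodes$area)
  ))
  invisible(x)
}
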