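#' The thirteen grid-compatible second-order vein angles
#'
#' Angles (degrees, measured from the perpendicular to the main vein) whose
#' tangents are small-integer ratios, so that a vein can be rasterized exactly
#' as a repeating staircase of lattice steps. These are the canonical sweep
#' vocabulary used throughout.
#'
#' @return A tibble with columns `theta` (printed degrees), `p` (longitudinal
#'   lattice units per period) and `q` (lateral units per period).
#' @export
paper_angles <- function() {
  tibble(
    theta = c(0, 7.13, 14.03, 21.80, 30.96, 36.87, 40.60,
              45, 49.40, 53.13, 59.06, 68.20, 75.96),
    p = c(0L, 1L, 1L, 2L, 3L, 3L, 6L, 1L, 7L, 4L, 5L, 5L, 4L),
    q = c(1L, 8L, 4L, 5L, 5L, 4L, 7L, 1L, 6L, 3L, 3L, 2L, 1L)
  )
}

#' Resolve a vein angle to its lattice step ratio
#'
#' Finds small integers (p, q) with tan(theta) = p/q so the requested angle is
#' exactly representable on the lattice. The 13 canonical angles resolve to
#' their printed ratios; any other angle is accepted if a ratio with
#' denominator at most `max_den` reproduces it to within 0.05 degrees.
#'
#' @param theta Angle in degrees, in `[0, 90)`.
#' @param max_den Largest integer tried for either leg of the ratio.
#' @return A list with `p`, `q` and the exact realised angle `theta_exact`.
#' @export
angle_ratio <- function(theta, max_den = 16L) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta >= 90) {
    abort("theta must be a single angle in [0, 90) degrees")
  }
  can <- paper_angles()
  hit <- which(abs(can$theta - theta) < 0.05)
  if (length(hit)) {
    k <- hit[1]
    return(list(p = can$p[k], q = can$q[k],
                theta_exact = atan2(can$p[k], can$q[k]) * 180 / pi))
  }
  tt <- tan(theta * pi / 180)
  for (q in seq_len(max_den)) {
    p <- round(q * tt)
    if (p > 4L * max_den) next
    th <- atan2(p, q) * 180 / pi
    if (abs(th - theta) < 0.05) {
      g <- .gcd(max(p, 1L), q)
      return(list(p = as.integer(p / max(g, 1)), q = as.integer(q / max(g, 1)),
                  theta_exact = th))
    }
  }
  abort(sprintf(
    "theta = %.3f deg is not grid-compatible (tan theta is not a small integer ratio)",
    theta
  ))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# One period of lattice steps realising slope p/q (longitudinal per lateral).
# Steps are rows (dj, di) with dj in {0, 1} (lateral, away from the main
# vein), di in {0, 1}. min(p, q) diagonal steps are Bresenham-interleaved with
# |p - q| axial steps of the dominant direction; when p > q the period is
# rotated to start on a diagonal step so a vein leaves the main vein at once.
.step_period <- function(p, q) {
  if (p == 0L) return(matrix(c(1L, 0L), ncol = 2, dimnames = list(NULL, c("dj", "di"))))
  if (q >= p) {
    k <- seq_len(q)
    diag <- floor(k * p / q) > floor((k - 1) * p / q)
    steps <- cbind(dj = rep(1L, q), di = as.integer(diag))
  } else {
    k <- seq_len(p)
    diag <- floor(k * q / p) > floor((k - 1) * q / p)
    steps <- cbind(dj = as.integer(diag), di = rep(1L, p))
    first_diag <- which(diag)[1]
    if (first_diag > 1L) steps <- steps[c(first_diag:p, seq_len(first_diag - 1L)), , drop = FALSE]
  }
  steps
}

#' Rasterize one second-order vein as a lattice staircase
#'
#' Walks a staircase of axial and diagonal lattice steps from a main-vein
#' attachment node toward the margin, with asymptotic direction exactly
#' `theta` degrees from the perpendicular (toward the apex), truncating at the
#' last node inside the outline.
#'
#' @param grid A [build_grid()] object.
#' @param i0 Longitudinal lattice index of the attachment node (on `j = 0`).
#' @param side `+1` for the right half-blade, `-1` for the left.
#' @param theta Vein angle in degrees (see [angle_ratio()]).
#' @return A tibble of directed lattice edges: `i1, j1, i2, j2, diag`
#'   (logical), `length` (m); zero rows if the vein exits immediately.
#' @export
rasterize_vein <- function(grid, i0, side, theta) {
  stopifnot(inherits(grid, "leaf_grid"), side %in% c(-1, 1))
  if (!grid$inside(as.integer(i0), 0L)) {
    abort("attachment node is outside the leaf")
  }
  r <- angle_ratio(theta)
  steps <- .step_period(r$p, r$q)
  # enough periods to cross the half-blade and then some
  nper <- ceiling((grid$jmax + 2L) / max(sum(steps[, "dj"]), 1L)) + 2L
  dj <- rep.int(steps[, "dj"], nper) * as.integer(side)
  di <- rep.int(steps[, "di"], nper)
  jj <- cumsum(dj)
  ii <- as.integer(i0) + cumsum(di)
  ok <- grid$inside(ii, jj)
  stop_at <- which(!ok)
  nkeep <- if (length(stop_at)) stop_at[1] - 1L else length(ii)
  if (nkeep == 0L) {
    return(tibble(i1 = integer(), j1 = integer(), i2 = integer(),
                  j2 = integer(), diag = logical(), length = numeric()))
  }
  i1 <- c(as.integer(i0), ii[seq_len(nkeep - 1L)])
  j1 <- c(0L, jj[seq_len(nkeep - 1L)])
  dg <- dj[seq_len(nkeep)] != 0L & di[seq_len(nkeep)] != 0L
  tibble(
    i1 = i1, j1 = j1, i2 = ii[seq_len(nkeep)], j2 = jj[seq_len(nkeep)],
    diag = dg, length = ifelse(dg, grid$spacing * sqrt(2), grid$spacing)
  )
}

# Attachment rows for interval pair (u1, u2) in lattice units, first
# attachment near 5 mm from the petiole.
.attach_rows <- function(grid, u1, u2) {
  i0 <- max(1L, as.integer(round(0.005 / grid$spacing)))
  rows <- integer(0)
  i <- i0
  k <- 0L
  while (i <= grid$ni) {
    rows <- c(rows, i)
    k <- k + 1L
    i <- i + if (k %% 2L == 1L) as.integer(u1) else as.integer(u2)
  }
  rows
}

# Unique-edge key for (i1,j1,i2,j2) with canonical endpoint order.
.edge_key <- function(i1, j1, i2, j2, jmax, ni) {
  a <- (i1 + 1L) * (2L * jmax + 3L) + (j1 + jmax + 1L)
  b <- (i2 + 1L) * (2L * jmax + 3L) + (j2 + jmax + 1L)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  lo * ((ni + 3) * (2 * jmax + 3)) + hi
}

#' Lay out the second-order veins
#'
#' Second-order veins attach to the main vein at a series of rows (first
#' attachment 5 mm from the petiole) and run, in mirrored left/right pairs,
#' as staircases at angle `theta` to the margin. In `constant_total_length`
#' mode the alternating attachment intervals (L_v1, L_v2) are found by integer
#' search over lattice-snapped pairs so the total length of the (deduplicated)
#' second-order edge set hits `target_length` to within `tol`; ties prefer
#' equal intervals. In `constant_spacing` mode the interval is fixed at `Lv`
#' and the total length floats.
#'
#' @param grid A [build_grid()] object.
#' @param theta Vein angle in degrees.
#' @param mode `"constant_total_length"` (default) or `"constant_spacing"`.
#' @param Lv Inter-vein interval in metres for `constant_spacing` (default
#'   0.010; the alternative setting is 0.015).
#' @param target_length Target total second-order length (m), default 0.74.
#' @param tol Admissible deviation from `target_length` (m), default 0.01.
#' @return List with `edges` (deduplicated tibble `i1,j1,i2,j2,diag,length`),
#'   `attach_rows`, `Lv1`, `Lv2` (m), `n_veins` (vein pairs count x 2) and
#'   `total_length` (m).
#' @export
layout_second_order_veins <- function(grid, theta,
                                      mode = c("constant_total_length", "constant_spacing"),
                                      Lv = 0.010, target_length = 0.74, tol = 0.01) {
  mode <- match.arg(mode)
  h <- grid$spacing

  # staircase edge tables per attachment row, one side (mirror for the other)
  per_row <- vector("list", grid$ni)
  keys_by_row <- vector("list", grid$ni)
  len_by_row <- numeric(grid$ni)
  for (i in seq_len(grid$ni)) {
    e <- rasterize_vein(grid, i, +1, theta)
    per_row[[i]] <- e
    keys_by_row[[i]] <- .edge_key(e$i1, e$j1, e$i2, e$j2, grid$jmax, grid$ni)
    len_by_row[i] <- sum(e$length)
  }
  union_total <- function(rows) {
    if (!length(rows)) return(0)
    keys <- unlist(keys_by_row[rows], use.names = FALSE)
    lens <- unlist(lapply(per_row[rows], `[[`, "length"), use.names = FALSE)
    2 * sum(lens[!duplicated(keys)]) # both sides, mirror-symmetric
  }

  if (mode == "constant_spacing") {
    u <- max(1L, as.integer(round(Lv / h)))
    rows <- .attach_rows(grid, u, u)
    Lv1 <- Lv2 <- u * h
  } else {
    # stage 1: integer search over alternating lattice-snapped intervals
    umax <- max(2L * as.integer(round(0.010 / h)) + 8L, 12L)
    best <- NULL
    for (u1 in seq_len(umax)) {
      for (u2 in seq_len(umax)) {
        rows <- .attach_rows(grid, u1, u2)
        tot <- union_total(rows)
        res <- abs(tot - target_length)
        cand <- list(u1 = u1, u2 = u2, rows = rows, tot = tot, res = res)
        if (is.null(best) ||
            res < best$res - 1e-12 ||
            (abs(res - best$res) < 1e-12 && abs(u1 - u2) < abs(best$u1 - best$u2))) {
          best <- cand
        }
      }
    }
    # stage 2: greedy per-row refinement -- individual attachment rows are
    # nudged along the main vein (intervals adjusted to different extents),
    # which changes each vein pair's length by 2*(w(z+dz) - w(z)) and gives
    # near-millimetre control of the total
    rows <- best$rows
    tot <- best$tot
    for (pass in seq_len(200L)) {
      if (abs(tot - target_length) <= tol / 2) break
      improved <- FALSE
      cand_best <- list(res = abs(tot - target_length))
      for (k in seq_along(rows)) {
        for (dlt in c(-2L, -1L, 1L, 2L)) {
          r2 <- rows
          r2[k] <- r2[k] + dlt
          if (r2[k] < 1L || r2[k] > grid$ni || anyDuplicated(r2)) next
          t2 <- union_total(sort(r2))
          if (abs(t2 - target_length) < cand_best$res - 1e-12) {
            cand_best <- list(res = abs(t2 - target_length), rows = sort(r2), tot = t2)
            improved <- TRUE
          }
        }
      }
      if (!improved) break
      rows <- cand_best$rows
      tot <- cand_best$tot
    }
    if (abs(tot - target_length) > tol) {
      abort(sprintf(
        "constant-total-length constraint unattainable: best total %.4f m (target %.2f +/- %.2f m)",
        tot, target_length, tol
      ))
    }
    Lv1 <- best$u1 * h
    Lv2 <- best$u2 * h
  }

  right <- dplyr::bind_rows(per_row[rows])
  left <- right
  left$j1 <- -left$j1
  left$j2 <- -left$j2
  edges <- dplyr::bind_rows(right, left)
  keys <- .edge_key(edges$i1, edges$j1, edges$i2, edges$j2, grid$jmax, grid$ni)
  edges <- edges[!duplicated(keys), ]

  list(
    edges = edges, attach_rows = rows, Lv1 = Lv1, Lv2 = Lv2,
    n_veins = 2L * length(rows), total_length = sum(edges$length)
  )
}

# Vein order of a lattice line. Line indices are 0-based (rows: i - 1,
# columns: |j|): every 6th line is order 3; the remaining even lines are
# order 4 and odd lines order 5 (swap with `swap45`).
.line_order <- function(idx, swap45 = FALSE) {
  o <- ifelse(idx %% 6L == 0L, 3L, ifelse(idx %% 2L == 0L, 4L, 5L))
  if (swap45) o <- ifelse(o == 4L, 5L, ifelse(o == 5L, 4L, o))
  o
}

#' Lay out the background vein lattice (orders 1, 3, 4, 5)
#'
#' The main (order-1) vein runs the full symmetry axis from petiole to apex.
#' Order-3 veins occupy every 6th lattice row and column; the remaining
#' lattice lines alternate between orders 4 and 5 (even/odd line index,
#' displaced by one grid unit in each direction), so every axial lattice edge
#' between adjacent inside nodes carries an order.
#'
#' @param grid A [build_grid()] object.
#' @param swap45 Swap the order-4/order-5 parity convention.
#' @return Tibble of axial edges `i1,j1,i2,j2,order,length`.
#' @export
layout_higher_order_veins <- function(grid, swap45 = FALSE) {
  nd <- grid$nodes
  h <- grid$spacing
  # lateral edges: (i, j) -- (i, j+1) on row line i
  lat <- nd[grid$inside(nd$i, nd$j + 1L), c("i", "j")]
  lat_order <- .line_order(lat$i - 1L, swap45)
  lat_e <- tibble(i1 = lat$i, j1 = lat$j, i2 = lat$i, j2 = lat$j + 1L,
                  order = lat_order, length = h)
  # longitudinal edges: (i, j) -- (i+1, j) on column line j
  lon <- nd[grid$inside(nd$i + 1L, nd$j), c("i", "j")]
  lon_order <- ifelse(lon$j == 0L, 1L, .line_order(abs(lon$j), swap45))
  lon_e <- tibble(i1 = lon$i, j1 = lon$j, i2 = lon$i + 1L, j2 = lon$j,
                  order = lon_order, length = h)
  dplyr::bind_rows(lat_e, lon_e)
}

#' Default per-order xylem conductivities and vein diameters
#'
#' Order-1 through order-5 xylem conductivities (m mmol s^-1 MPa^-1) and vein
#' diameters (m) of the core parameterisation. Per-edge conductance is
#' conductivity / edge length.
#'
#' @return List with numeric vectors `conductivity` and `diameter`, indexed by
#'   vein order.
#' @export
default_conductivities <- function() {
  list(
    conductivity = c(1.00e-2, 5.00e-4, 6.00e-5, 4.00e-5, 4.00e-6),
    diameter = c(15.50e-6, 11.30e-6, 7.50e-6, 7.20e-6, 4.34e-6)
  )
}

#' Assign per-edge conductances from vein order
#'
#' Computes, for every edge of a layout, the xylem conductance
#' `K_xyl = conductivity[order] / length`, the phloem conductance
#' `K_ph = phloem_factor * K_xyl`, and the sucrose diffusive conductance
#' `G_ph = D_su * A_ph / length` with `A_ph = pi d^2 / 4` from the per-order
#' vein diameter.
#'
#' @param layout A `vein_layout` object.
#' @param params A [model_params()] object (supplies `conductivity`,
#'   `diameter`, `phloem_factor`, `D_su`).
#' @return The layout with refreshed `K_xyl`, `K_ph`, `G_ph` edge columns.
#' @export
assign_conductances <- function(layout, params) {
  stopifnot(inherits(layout, "vein_layout"))
  e <- layout$edges
  if (anyNA(e$order)) abort("edge with no vein order")
  cond <- params$conductivity
  diam <- params$diameter
  e$K_xyl <- cond[e$order] / e$length
  e$K_ph <- params$phloem_factor * e$K_xyl
  e$G_ph <- params$D_su * (pi * diam[e$order]^2 / 4) / e$length
  layout$edges <- e
  layout$params_tag <- list(
    conductivity = cond, diameter = diam, phloem_factor = params$phloem_factor,
    D_su = params$D_su
  )
  layout
}

#' Build a complete vein layout for a leaf
#'
#' Full constructor: node lattice, background lattice veins (orders 1, 3-5),
#' angled second-order veins, edge merging (where several orders share an
#' edge the lowest order, i.e. highest conductivity, wins), the external
#' petiole conduit, and per-edge conductances.
#'
#' @inheritParams build_grid
#' @inheritParams layout_second_order_veins
#' @param params A [model_params()] object; its conductivity table is used.
#' @param swap45 Order-4/5 parity convention switch.
#' @return An object of class `vein_layout`: list with `grid`, `nodes`
#'   (tibble, incl. petiole row with zero area), `edges` (tibble `from, to,
#'   i1,j1,i2,j2, order, length, K_xyl, K_ph, G_ph`), `theta`, `mode`,
#'   `order2` (the [layout_second_order_veins()] summary) and
#'   `length_by_order`.
#' @examples
#' lay <- build_vein_layout(make_leaf_shape("reference"), spacing = 0.004, theta = 45)
#' lay$order2$total_length
#' @export
build_vein_layout <- function(shape, spacing = 0.002, theta = 0,
                              mode = c("constant_total_length", "constant_spacing"),
                              Lv = 0.010, params = model_params(),
                              target_length = 0.74, tol = 0.01, swap45 = FALSE) {
  mode <- match.arg(mode)
  grid <- if (inherits(shape, "leaf_grid")) shape else build_grid(shape, spacing)
  shape <- grid$shape

  bg <- layout_higher_order_veins(grid, swap45 = swap45)
  o2 <- layout_second_order_veins(grid, theta, mode = mode, Lv = Lv,
                                  target_length = target_length, tol = tol)
  o2e <- o2$edges
  if (nrow(o2e)) {
    o2e <- tibble(i1 = o2e$i1, j1 = o2e$j1, i2 = o2e$i2, j2 = o2e$j2,
                  order = 2L, length = o2e$length)
  } else {
    o2e <- bg[0, ]
  }
  edges <- dplyr::bind_rows(bg, o2e)
  keys <- .edge_key(edges$i1, edges$j1, edges$i2, edges$j2, grid$jmax, grid$ni)
  # lowest order wins on shared edges
  edges <- edges[order(keys, edges$order), ]
  keys <- sort(keys)
  edges <- edges[!duplicated(keys), ]

  edges$from <- grid$id_of(edges$i1, edges$j1)
  edges$to <- grid$id_of(edges$i2, edges$j2)
  if (anyNA(edges$from) || anyNA(edges$to)) abort("edge endpoint outside leaf")

  # petiole conduit: external petiole node -> first internal main-vein node
  pet <- tibble(
    i1 = 0L, j1 = 0L, i2 = 1L, j2 = 0L, order = 1L,
    length = grid$petiole_length, from = grid$petiole, to = grid$first_node
  )
  edges <- dplyr::bind_rows(edges, pet)

  nodes <- dplyr::bind_rows(
    grid$nodes,
    tibble(node = grid$petiole, i = 0L, j = 0L, x = 0, z = 0, area = 0)
  )

  layout <- structure(
    list(
      grid = grid, shape = shape, nodes = nodes,
      edges = edges[, c("from", "to", "i1", "j1", "i2", "j2", "order", "length")],
      theta = theta, mode = mode, spacing = grid$spacing,
      petiole = grid$petiole, first_node = grid$first_node,
      order2 = o2[c("attach_rows", "Lv1", "Lv2", "n_veins", "total_length")],
      length_by_order = NULL
    ),
    class = "vein_layout"
  )
  layout$length_by_order <- with(
    layout$edges, tapply(length, order, sum)
  )
  assign_conductances(layout, params)
}

#' @export
print.vein_layout <- function(x, ...) {
  cat(sprintf(
    "<vein_layout '%s'>  theta = %.2f deg (%s), %d nodes, %d edges, order-2 total %.3f m (%d veins)\n",
    x$shape$variant, x$theta, x$mode, nrow(x$nodes), nrow(x$edges),
    x$order2$total_length, x$order2$n_veins
  ))
  invisible(x)
}
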