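#' Edge flux primitives
#'
#' Signed node-centric fluxes of the coupled network model. The convention
#' throughout is that a flux returned for node `ij` and neighbour `d` is
#' positive when it is an influx *into* `ij`.
#'
#' * `xylem_edge_flux()`: Darcy flux `K * (p_d - p_ij)` (mmol s^-1).
#' * `phloem_edge_flux()`: Darcy flux with an osmotic contribution,
#'   `K * ((p_d - p_ij) - sigma * R * T * (C_d - C_ij))`; with the default
#'   lateral reflection coefficient of 0 it reduces to the xylem form.
#' * `cross_flux()`: water flux into the xylem node from its phloem partner,
#'   `K_c * ((p_ph - sigma_c * R * T * C_ph) - p_xyl)`; the phloem node
#'   receives the negation. With `C_ph > 0` and equal pressures this is
#'   negative: the osmotic pull of phloem sap draws water out of the xylem.
#' * `transpiration_flux()`: `E * a_ij` (negative for a transpiring leaf).
#' * `sucrose_loading()`: `Lambda * a_ij` (mol s^-1).
#' * `sucrose_edge_flux()`: convective plus diffusive sucrose flux
#'   `(1 - sigma) * v_mu * F_ph * C_conv + G * (C_d - C_ij)` (mol s^-1). Under
#'   the `"literal"` scheme the convective factor is always `C_ij`; under
#'   `"upwind"` it is the concentration of the donor node (the node the water
#'   flows from: the neighbour when `F_ph >= 0`, the centre node otherwise).
#'
#' @param K,K_c,G Conductances (mmol s^-1 MPa^-1; `G` in m^3 s^-1).
#' @param p_ij,p_d,p_ph,p_xyl Pressures (MPa).
#' @param C_ij,C_d,C_ph Sucrose concentrations (mol m^-3).
#' @param E Transpiration rate (mmol s^-1 m^-2); `a` node area (m^2).
#' @param Lambda Sucrose loading rate (mol s^-1 m^-2).
#' @param F_ph Phloem water flux into the centre node (mmol s^-1).
#' @param params A [model_params()] object.
#' @param scheme Sucrose convection scheme, defaulting to `params$sucrose_scheme`.
#' @return Numeric flux, vectorised over the inputs.
#' @name edge_fluxes
NULL

#' @rdname edge_fluxes
#' @export
xylem_edge_flux <- function(K, p_ij, p_d) K * (p_d - p_ij)

#' @rdname edge_fluxes
#' @export
phloem_edge_flux <- function(K, p_ij, p_d, C_ij, C_d, params) {
  K * ((p_d - p_ij) - params$sigma_lateral * params$R * params$T * (C_d - C_ij))
}

#' @rdname edge_fluxes
#' @export
cross_flux <- function(K_c, p_ph, C_ph, p_xyl, params) {
  K_c * ((p_ph - params$sigma_cross * params$R * params$T * C_ph) - p_xyl)
}

#' @rdname edge_fluxes
#' @export
transpiration_flux <- function(E, a) E * a

#' @rdname edge_fluxes
#' @export
sucrose_loading <- function(Lambda, a) Lambda * a

#' @rdname edge_fluxes
#' @export
sucrose_edge_flux <- function(F_ph, C_ij, C_d, G, params,
                              scheme = params$sucrose_scheme) {
  C_conv <- if (identical(scheme, "upwind")) ifelse(F_ph >= 0, C_d, C_ij) else C_ij
  (1 - params$sigma_lateral) * params$v_mu * F_ph * C_conv + G * (C_d - C_ij)
}

# ---------------------------------------------------------------------------
# Steady-state system assembly. Unknown vector x = [p_xyl; p_ph; C], each
# block over all nodes (petiole last). Per inside node the residuals are the
# three conservation laws; the petiole carries two Dirichlet rows and the
# zero-Neumann sucrose row C_pet - C_first = 0.
# ---------------------------------------------------------------------------

#' Build the transport system operator for a layout
#'
#' Precomputes the sparse network Laplacians, forcing vectors, residual
#' scales and constant Jacobian entries of the steady-state system. Used by
#' [solve_steady()] and [assemble_residual()]; exposed for advanced use.
#'
#' @param layout A `vein_layout` (or a compatible toy layout, see
#'   [toy_layout()]).
#' @param params A [model_params()] object.
#' @return An opaque list of class `transport_system`.
#' @export
build_transport_system <- function(layout, params) {
  nodes <- layout$nodes
  n <- nrow(nodes)
  pet <- layout$petiole
  first <- layout$first_node
  e <- layout$edges
  if (is.null(e$K_xyl)) {
    layout <- assign_conductances(layout, params)
    e <- layout$edges
  }

  # directed edge table (both orientations); `from` is the centre node
  de <- tibble(
    from = c(e$from, e$to), to = c(e$to, e$from),
    K_x = rep(e$K_xyl, 2), K_p = rep(e$K_ph, 2), G = rep(e$G_ph, 2)
  )

  lap <- function(w) {
    sparseMatrix(
      i = c(de$from, de$from), j = c(de$to, de$from), x = c(w, -w),
      dims = c(n, n)
    )
  }
  A_x <- lap(de$K_x)
  A_p <- lap(de$K_p)
  G_lap <- lap(de$G)

  RT <- params$R * params$T
  a <- nodes$area
  E_force <- params$E * a
  Lam <- loading_rates(params, nodes, layout$shape$length) * a
  Lam[pet] <- 0
  Kc <- rep(params$K_c, n)
  Kc[pet] <- 0

  inside <- setdiff(seq_len(n), pet)
  din <- de[de$from != pet, ]

  # constant Jacobian triplets (rows: 1..n xylem, n+1..2n phloem, 2n+1..3n sucrose)
  i_fx <- c(din$from, din$from, inside, inside, inside)
  j_fx <- c(din$to, din$from, inside, n + inside, 2L * n + inside)
  x_fx <- c(din$K_x, -din$K_x, -Kc[inside], Kc[inside], -Kc[inside] * RT)

  i_fp <- c(n + din$from, n + din$from, n + inside, n + inside, n + inside)
  j_fp <- c(n + din$to, n + din$from, n + inside, 2L * n + inside, inside)
  x_fp <- c(din$K_p, -din$K_p, -Kc[inside], Kc[inside] * RT, Kc[inside])

  i_fs <- c(2L * n + din$from, 2L * n + din$from)
  j_fs <- c(2L * n + din$to, 2L * n + din$from)
  x_fs <- c(din$G, -din$G)

  i_bc <- c(pet, n + pet, 2L * n + pet, 2L * n + pet)
  j_bc <- c(pet, n + pet, 2L * n + pet, 2L * n + first)
  x_bc <- c(1, 1, 1, -1)

  fixed <- list(
    i = c(i_fx, i_fp, i_fs, i_bc),
    j = c(j_fx, j_fp, j_fs, j_bc),
    x = c(x_fx, x_fp, x_fs, x_bc)
  )

  # residual scales per row (pressure scale 0.1 MPa, concentration 100 mol/m^3)
  ps <- 0.1
  cs <- 100
  degx <- abs(Matrix::diag(A_x))
  degp <- abs(Matrix::diag(A_p))
  degg <- abs(Matrix::diag(G_lap))
  s1 <- degx * ps + Kc * (ps + RT * cs) + abs(E_force)
  s2 <- degp * ps + Kc * (ps + RT * cs)
  s3 <- degg * cs + params$v_mu * degp * ps * cs + abs(Lam)
  s1[pet] <- ps
  s2[pet] <- ps
  s3[pet] <- cs
  row_scale <- pmax(c(s1, s2, s3), 1e-300)
  col_scale <- rep(c(1, 1, cs), each = n)

  structure(
    list(
      n = n, pet = pet, first = first, inside = inside,
      de = de, din = din, A_x = A_x, A_p = A_p, G_lap = G_lap,
      RT = RT, a = a, E_force = E_force, Lam = Lam, Kc = Kc,
      params = params, fixed = fixed,
      row_scale = row_scale, col_scale = col_scale
    ),
    class = "transport_system"
  )
}

# raw residual vector of length 3n given unknown vector x = [p_x; p_p; C]
.residual_raw <- function(sys, x) {
  n <- sys$n
  p_x <- x[seq_len(n)]
  p_p <- x[n + seq_len(n)]
  C <- x[2L * n + seq_len(n)]
  pr <- sys$params
  pet <- sys$pet

  Fc <- sys$Kc * ((p_p - pr$sigma_cross * sys$RT * C) - p_x)
  r1 <- as.numeric(sys$A_x %*% p_x) + sys$E_force + Fc
  r2 <- as.numeric(sys$A_p %*% p_p) - Fc

  din <- sys$din
  Fe <- phloem_edge_flux(din$K_p, p_p[din$from], p_p[din$to],
                         C[din$from], C[din$to], pr)
  Se <- sucrose_edge_flux(Fe, C[din$from], C[din$to], din$G, pr)
  r3 <- sys$Lam
  agg <- rowsum(Se, din$from)
  r3[as.integer(rownames(agg))] <- r3[as.integer(rownames(agg))] + agg[, 1]

  r1[pet] <- p_x[pet] - pr$petiole_p_xyl
  r2[pet] <- p_p[pet] - pr$petiole_p_ph
  r3[pet] <- C[pet] - C[sys$first]
  c(r1, r2, r3)
}

# sparse Jacobian at x (raw units)
.jacobian_raw <- function(sys, x) {
  n <- sys$n
  p_p <- x[n + seq_len(n)]
  C <- x[2L * n + seq_len(n)]
  pr <- sys$params
  din <- sys$din
  sig <- pr$sigma_lateral
  vfac <- (1 - sig) * pr$v_mu

  Fe <- phloem_edge_flux(din$K_p, p_p[din$from], p_p[din$to],
                         C[din$from], C[din$to], pr)
  C_use <- if (identical(pr$sucrose_scheme, "upwind")) {
    ifelse(Fe >= 0, C[din$to], C[din$from])
  } else {
    C[din$from]
  }
  donor <- if (identical(pr$sucrose_scheme, "upwind")) {
    ifelse(Fe >= 0, din$to, din$from)
  } else {
    din$from
  }

  rows <- 2L * n + din$from
  dpp <- vfac * din$K_p * C_use
  i_v <- c(rows, rows, rows)
  j_v <- c(n + din$to, n + din$from, 2L * n + donor)
  x_v <- c(dpp, -dpp, vfac * Fe)
  if (sig != 0) {
    dFdCt <- -din$K_p * sig * sys$RT
    i_v <- c(i_v, rows, rows)
    j_v <- c(j_v, 2L * n + din$to, 2L * n + din$from)
    x_v <- c(x_v, vfac * C_use * dFdCt, -vfac * C_use * dFdCt)
  }

  sparseMatrix(
    i = c(sys$fixed$i, i_v), j = c(sys$fixed$j, j_v),
    x = c(sys$fixed$x, x_v), dims = c(3L * n, 3L * n)
  )
}

#' Assemble the steady-state residual
#'
#' Evaluates, for a given network state, the three conservation residuals at
#' every node: xylem water balance (sum of the eight Darcy fluxes plus
#' transpiration plus the cross flux), phloem water balance (Darcy/osmotic
#' fluxes minus the cross flux) and sucrose balance (convective plus
#' diffusive edge fluxes plus loading). The petiole rows hold the two
#' Dirichlet pressure residuals and the zero-Neumann sucrose residual
#' `C_petiole - C_first`.
#'
#' @param layout A `vein_layout` or toy layout.
#' @param params A [model_params()] object.
#' @param state List with numeric vectors `p_xyl`, `p_ph` (MPa) and `C`
#'   (mol m^-3), one entry per node (petiole included).
#' @return A tibble with one row per node: `node`, `r_xyl`, `r_ph` (mmol
#'   s^-1), `r_suc` (mol s^-1).
#' @export
assemble_residual <- function(layout, params, state) {
  sys <- build_transport_system(layout, params)
  n <- sys$n
  stopifnot(length(state$p_xyl) == n, length(state$p_ph) == n,
            length(state$C) == n)
  r <- .residual_raw(sys, c(state$p_xyl, state$p_ph, state$C))
  tibble(
    node = seq_len(n),
    r_xyl = r[seq_len(n)],
    r_ph = r[n + seq_len(n)],
    r_suc = r[2L * n + seq_len(n)]
  )
}

# Balance-closure diagnostics at a (near-)converged state.
.balance_report <- function(sys, x) {
  n <- sys$n
  p_x <- x[seq_len(n)]
  p_p <- x[n + seq_len(n)]
  C <- x[2L * n + seq_len(n)]
  pr <- sys$params
  pet <- sys$pet
  first <- sys$first

  pe <- sys$de[sys$de$from == first & sys$de$to == pet, ]
  # influx into the first node from the petiole = inflow into the leaf
  xyl_inflow <- xylem_edge_flux(pe$K_x, p_x[first], p_x[pet])
  ph_inflow <- phloem_edge_flux(pe$K_p, p_p[first], p_p[pet], C[first], C[pet], pr)
  Fpe <- ph_inflow
  suc_export <- -sucrose_edge_flux(Fpe, C[first], C[pet], pe$G, pr)

  Fc <- sys$Kc * ((p_p - pr$sigma_cross * sys$RT * C) - p_x)
  transp <- sum(sys$E_force)
  load <- sum(sys$Lam)

  list(
    xylem_petiole_inflow = xyl_inflow,
    total_transpiration = transp,
    total_cross_to_phloem = -sum(Fc),
    xylem_closure_gap = xyl_inflow + transp + sum(Fc),
    phloem_petiole_outflow = -ph_inflow,
    phloem_closure_gap = -ph_inflow - (-sum(Fc)),
    sucrose_export = suc_export,
    total_loading = load,
    sucrose_conservation_gap = suc_export - load
  )
}
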