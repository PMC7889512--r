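#' Solver settings
#'
#' Controls for the damped Newton iteration of [solve_steady()].
#'
#' @param tol Convergence tolerance on the maximum scaled residual (residuals
#'   are scaled per equation class by conductance-times-pressure-scale and
#'   forcing magnitudes), default 1e-10.
#' @param max_iter Maximum Newton iterations per continuation stage.
#' @param C_init Initial sucrose concentration guess (mol m^-3), default 100
#'   (within the physical regime of the solved fields, which average
#'   ~160-180 mol m^-3). Pressures are initialised at the petiole values.
#' @param continuation_steps Number of homotopy stages used by the fallback
#'   (and by [brute_force_oracle()]); the cross-conductance and loading rate
#'   are ramped from 0 (where the system is linear) to their target values.
#' @param seed Seed for the perturbed-restart fallback (the solve itself is
#'   deterministic).
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(tol = 1e-10, max_iter = 50L, C_init = 100,
                            continuation_steps = 5L, seed = 1L) {
  stopifnot(tol > 0, max_iter >= 1, C_init >= 0)
  structure(
    list(tol = tol, max_iter = max_iter, C_init = C_init,
         continuation_steps = continuation_steps, seed = seed),
    class = "solver_settings"
  )
}

# Damped Newton on the scaled system. Returns list(x, converged, iterations,
# residual)
.newton <- function(sys, x0, settings) {
  rs_of <- function(x) .residual_raw(sys, x) / sys$row_scale
  x <- x0
  rs <- rs_of(x)
  best <- max(abs(rs))
  for (it in seq_len(settings$max_iter)) {
    if (best < settings$tol) {
      return(list(x = x, converged = TRUE, iterations = it - 1L, residual = best))
    }
    J <- .jacobian_raw(sys, x)
    Js <- Diagonal(x = 1 / sys$row_scale) %*% J %*% Diagonal(x = sys$col_scale)
    dxs <- tryCatch(
      as.numeric(Matrix::solve(Js, -rs)),
      error = function(e) {
        tryCatch(as.numeric(Matrix::qr.coef(Matrix::qr(Js), -rs)),
                 error = function(e2) NULL)
      }
    )
    if (is.null(dxs) || any(!is.finite(dxs))) {
      return(list(x = x, converged = FALSE, iterations = it, residual = best))
    }
    dx <- sys$col_scale * dxs
    # backtracking line search on the scaled residual norm
    step <- 1
    repeat {
      xn <- x + step * dx
      rn <- rs_of(xn)
      if (max(abs(rn)) < best * (1 - 0.25 * step) || max(abs(rn)) < settings$tol) {
        x <- xn
        rs <- rn
        best <- max(abs(rn))
        break
      }
      step <- step / 2
      if (step < 1e-6) {
        return(list(x = x, converged = FALSE, iterations = it, residual = best))
      }
    }
  }
  list(x = x, converged = best < settings$tol,
       iterations = settings$max_iter, residual = best)
}

.initial_guess <- function(sys, settings) {
  n <- sys$n
  pr <- sys$params
  c(rep(pr$petiole_p_xyl, n), rep(pr$petiole_p_ph, n), rep(settings$C_init, n))
}

#' Solve the coupled steady state
#'
#' Solves the assembled nonlinear system (xylem water balance, phloem
#' water balance, sucrose balance, plus the petiole boundary rows) for the
#' pressures and sucrose concentration at every node, by a damped Newton
#' method with an analytic sparse Jacobian. On failure, a homotopy fallback
#' ramps the cross-conduit conductance and the loading rate from zero (where
#' the problem is linear) to their target values in stages, re-starting
#' Newton from each intermediate solution.
#'
#' @param layout A `vein_layout` or toy layout.
#' @param params A [model_params()] object.
#' @param settings A [solver_settings()] object.
#' @param init Optional initial unknown vector `c(p_xyl, p_ph, C)`.
#' @return An object of class `leaf_steady`: list with `nodes` (tibble:
#'   `node, i, j, x, z, area, p_xyl, p_ph, C`), `layout` metadata, `params`,
#'   and `diagnostics` (convergence, iteration count, final scaled residual,
#'   balance closures including the literal-scheme sucrose conservation gap).
#' @examples
#' lay <- build_vein_layout(make_leaf_shape("reference"), spacing = 0.004, theta = 45)
#' fit <- solve_steady(lay, model_params())
#' glance(fit)
#' @export
solve_steady <- function(layout, params = model_params(),
                         settings = solver_settings(), init = NULL) {
  sys <- build_transport_system(layout, params)
  x0 <- if (is.null(init)) .initial_guess(sys, settings) else init
  res <- .newton(sys, x0, settings)

  if (!res$converged) {
    # continuation in (K_c, Lambda) from the linear limit
    x <- x0
    ts <- seq(0, 1, length.out = settings$continuation_steps + 1L)
    ok <- TRUE
    for (t in ts) {
      pr_t <- params
      pr_t$K_c <- t * params$K_c
      pr_t$Lambda <- t * params$Lambda
      sys_t <- build_transport_system(layout, pr_t)
      st <- .newton(sys_t, x, settings)
      x <- st$x
      ok <- st$converged
      if (!ok) break
    }
    if (ok) res <- .newton(sys, x, settings)
    if (!res$converged) {
      abort(sprintf(
        "steady-state solve did not converge (max scaled residual %.3e after continuation)",
        res$residual
      ))
    }
  }

  n <- sys$n
  x <- res$x
  C <- x[2L * n + seq_len(n)]
  if (min(C) < -1e-6 * max(abs(C), 1)) {
    warning(sprintf(
      "negative sucrose concentrations at the solution (min %.3g mol m^-3): outside the model's physical regime",
      min(C)
    ), call. = FALSE)
  }

  nodes <- layout$nodes
  nodes$p_xyl <- x[seq_len(n)]
  nodes$p_ph <- x[n + seq_len(n)]
  nodes$C <- C

  structure(
    list(
      nodes = nodes,
      petiole = layout$petiole,
      spacing = layout$spacing,
      meta = list(
        variant = layout$shape$variant, theta = layout$theta,
        mode = layout$mode, n_inside = n - 1L
      ),
      params = params,
      diagnostics = c(
        list(converged = res$converged, iterations = res$iterations,
             residual = res$residual),
        .balance_report(sys, x)
      )
    ),
    class = "leaf_steady"
  )
}

#' @export
print.leaf_steady <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<leaf_steady '%s' theta = %.2f>  %d nodes, %d iterations, max scaled residual %.2e\n",
    x$meta$variant, x$meta$theta, x$meta$n_inside, d$iterations, d$residual
  ))
  cat(sprintf(
    "  <p_xyl> = %.4f MPa, <p_ph> = %.4f MPa, <C> = %.2f mol m^-3\n",
    area_average(x, "p_xyl"), area_average(x, "p_ph"), area_average(x, "C")
  ))
  invisible(x)
}

#' Dense homotopy-Newton reference solver for small networks
#'
#' Solves the same residual system as [solve_steady()] but by an independent
#' numerical route: homotopy continuation in the cross-conduit conductance
#' and loading rate starting from the linear (decoupled, unloaded) problem,
#' with a dense Newton iteration whose Jacobian is obtained by central finite
#' differences. Intended as a test oracle on networks of up to a few dozen
#' nodes.
#'
#' @inheritParams solve_steady
#' @param stages Number of homotopy stages.
#' @return List with `x` (the unknown vector `c(p_xyl, p_ph, C)`),
#'   `converged` and `residual`.
#' @export
brute_force_oracle <- function(layout, params = model_params(),
                               settings = solver_settings(), stages = 5L) {
  n0 <- nrow(layout$nodes)
  if (n0 > 60) abort("brute_force_oracle is for small networks (<= 60 nodes)")
  x <- NULL
  for (t in seq(0, 1, length.out = stages + 1L)) {
    pr_t <- params
    pr_t$K_c <- t * params$K_c
    pr_t$Lambda <- t * params$Lambda
    sys <- build_transport_system(layout, pr_t)
    if (is.null(x)) x <- .initial_guess(sys, settings)
    f <- function(xx) .residual_raw(sys, xx) / sys$row_scale
    for (it in seq_len(settings$max_iter)) {
      rs <- f(x)
      if (max(abs(rs)) < settings$tol) break
      Jd <- pracma::jacobian(f, x)
      dx <- tryCatch(base::solve(Jd, -rs), error = function(e) NULL)
      if (is.null(dx) || any(!is.finite(dx))) break
      x <- x + dx
    }
  }
  sys <- build_transport_system(layout, params)
  resid <- max(abs(.residual_raw(sys, x) / sys$row_scale))
  if (resid > 1e2 * settings$tol) {
    abort(sprintf("oracle failed to converge (scaled residual %.3e)", resid))
  }
  list(x = x, converged = TRUE, residual = resid)
}

#' Closed-form xylem pressures on a uniform transpiring chain
#'
#' For a chain of `n` nodes hanging off a Dirichlet boundary node at pressure
#' `p0`, with uniform edge conductance `K_edge` and uniform transpiration
#' `E * a` at every node, the Darcy balance telescopes to
#' \deqn{p_m = p_0 + (E a / K) \sum_{k=1}^{m} (n - k + 1),}
#' a monotone decreasing sequence when `E < 0`.
#'
#' @param n Number of chain nodes (excluding the boundary node).
#' @param K_edge Edge conductance (mmol s^-1 MPa^-1).
#' @param E Transpiration rate (mmol s^-1 m^-2); `a` per-node area (m^2).
#' @param p0 Boundary pressure (MPa).
#' @param a Per-node area (m^2).
#' @return Numeric vector of node pressures `p_1 .. p_n`.
#' @export
xylem_chain_closed_form <- function(n, K_edge, E, a, p0 = 0) {
  f <- E * a / K_edge
  p0 + f * cumsum(n - seq_len(n) + 1)
}
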