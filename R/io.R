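#' Export and import a vein layout
#'
#' Writes the layout as a plain-text interchange set: `nodes.csv` (`node, i,
#' j, x, z, area`), `edges.csv` (`from, to, i1, j1, i2, j2, order, length,
#' K_xyl, K_ph, G_ph`) and `header.json` (shape, angle, spacing, mode and
#' second-order summary). `read_layout()` restores a layout usable by
#' [solve_steady()] (geometry closures are not reconstructed).
#'
#' @param layout A `vein_layout`.
#' @param dir Output directory (created if missing).
#' @return `write_layout()` returns the directory invisibly; `read_layout()`
#'   a `vein_layout`.
#' @export
write_layout <- function(layout, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(layout$nodes, file.path(dir, "nodes.csv"))
  readr::write_csv(layout$edges, file.path(dir, "edges.csv"))
  hdr <- list(
    variant = layout$shape$variant, length = layout$shape$length,
    width = layout$shape$width %||% NA, area = layout$shape$area %||% NA,
    theta = layout$theta, mode = layout$mode, spacing = layout$spacing,
    petiole = layout$petiole, first_node = layout$first_node,
    order2 = layout$order2[c("Lv1", "Lv2", "n_veins", "total_length")]
  )
  jsonlite::write_json(hdr, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_layout
#' @export
read_layout <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"), simplifyVector = TRUE)
  nodes <- readr::read_csv(file.path(dir, "nodes.csv"), show_col_types = FALSE)
  edges <- readr::read_csv(file.path(dir, "edges.csv"), show_col_types = FALSE)
  structure(
    list(
      nodes = nodes, edges = edges, petiole = hdr$petiole,
      first_node = hdr$first_node, theta = hdr$theta, mode = hdr$mode,
      spacing = hdr$spacing,
      shape = list(variant = hdr$variant, length = hdr$length,
                   width = hdr$width, area = hdr$area),
      order2 = as.list(hdr$order2)
    ),
    class = "vein_layout"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a solved state
#'
#' Writes the node table (`i, j, x, z, area, p_xyl, p_ph, C`, full double
#' precision) and, optionally, a per-edge flux table (`from, to, order,
#' F_xyl, F_ph, S`, fluxes signed into `from`).
#'
#' @param state A [solve_steady()] result.
#' @param path Output CSV path for the node table.
#' @param layout If supplied, per-edge fluxes are written next to `path` as
#'   `<path minus .csv>_edges.csv`.
#' @return The node path, invisibly.
#' @export
write_state <- function(state, path, layout = NULL) {
  readr::write_csv(state$nodes, path)
  if (!is.null(layout)) {
    nd <- state$nodes
    e <- layout$edges
    pr <- state$params
    F_x <- xylem_edge_flux(e$K_xyl, nd$p_xyl[e$from], nd$p_xyl[e$to])
    F_p <- phloem_edge_flux(e$K_ph, nd$p_ph[e$from], nd$p_ph[e$to],
                            nd$C[e$from], nd$C[e$to], pr)
    S <- sucrose_edge_flux(F_p, nd$C[e$from], nd$C[e$to], e$G_ph, pr)
    ef <- tibble(from = e$from, to = e$to, order = e$order,
                 F_xyl = F_x, F_ph = F_p, S = S)
    readr::write_csv(ef, sub("\\.csv$", "_edges.csv", path))
  }
  invisible(path)
}

#' Run configuration
#'
#' `default_config()` returns the fully-resolved default configuration (every
#' key at its core value); `read_run_config()` reads a YAML or JSON config
#' file and merges it over the defaults, rejecting unknown keys.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A nested named list with blocks `shape`, `veins`, `params`,
#'   `solver`, `experiment`, `output`.
#' @export
default_config <- function() {
  list(
    shape = list(variant = "reference", spacing_mm = 2.0),
    veins = list(theta_deg = 0.0, mode = "constant_total_length", Lv_mm = 10.0,
                 target_length_m = 0.74, swap45 = FALSE),
    params = list(
      T = 293, R = 8.31e-6, D_su = 5.22e-10, v_mu = 18.0e-9, K_c = 0.50,
      E = -2.00, Lambda = 2.78e-7, loading = "uniform",
      petiole_p_xyl = 0.00, petiole_p_ph = 0.20, phloem_factor = 0.03,
      sucrose_scheme = "literal",
      conductivity = default_conductivities()$conductivity,
      diameter = default_conductivities()$diameter
    ),
    solver = list(tol = 1e-10, max_iter = 50, C_init = 100,
                  continuation_steps = 5, seed = 1),
    experiment = list(shapes = "reference", angles = "paper13",
                      k2_multiplier = 1.0),
    output = list(dir = ".")
  )
}

#' @rdname default_config
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  def <- default_config()
  bad <- setdiff(names(raw), names(def))
  if (length(bad)) abort(paste("unknown config block(s):", paste(bad, collapse = ", ")))
  for (blk in names(raw)) {
    badk <- setdiff(names(raw[[blk]]), names(def[[blk]]))
    if (length(badk)) {
      abort(sprintf("unknown key(s) in '%s': %s", blk, paste(badk, collapse = ", ")))
    }
    def[[blk]] <- utils::modifyList(def[[blk]], raw[[blk]])
  }
  def
}

.config_params <- function(cfg) {
  p <- cfg$params
  k <- as.numeric(p$conductivity)
  k[2] <- k[2] * cfg$experiment$k2_multiplier
  model_params(
    T = p$T, R = p$R, D_su = p$D_su, v_mu = p$v_mu, K_c = p$K_c, E = p$E,
    Lambda = p$Lambda, loading = p$loading,
    petiole_p_xyl = p$petiole_p_xyl, petiole_p_ph = p$petiole_p_ph,
    phloem_factor = p$phloem_factor, sucrose_scheme = p$sucrose_scheme,
    conductivity = k, diameter = as.numeric(p$diameter)
  )
}

.config_angles <- function(cfg) {
  a <- cfg$experiment$angles
  if (identical(a, "paper13")) paper_angles()$theta else as.numeric(a)
}

#' Run a configured build / solve / sweep
#'
#' Programmatic equivalents of the command-line entry points: `run_build()`
#' writes the layout files for the configured (shape, angle); `run_solve()`
#' solves the steady state and writes node/edge tables plus a JSON run
#' report; `run_sweep()` executes the angle sweep over the configured shapes
#' and writes one sweep CSV per shape plus a peak summary.
#'
#' @param config A configuration list (see [default_config()]).
#' @return `run_build()` the layout; `run_solve()` the `leaf_steady`;
#'   `run_sweep()` a named list of sweep tibbles. All invisibly.
#' @export
run_build <- function(config = default_config()) {
  params <- .config_params(config)
  lay <- build_vein_layout(
    make_leaf_shape(config$shape$variant),
    spacing = config$shape$spacing_mm / 1000,
    theta = config$veins$theta_deg, mode = config$veins$mode,
    Lv = config$veins$Lv_mm / 1000,
    target_length = config$veins$target_length_m,
    params = params, swap45 = isTRUE(config$veins$swap45)
  )
  dir <- file.path(config$output$dir,
                   sprintf("layout_%s_theta%05.2f", config$shape$variant,
                           config$veins$theta_deg))
  write_layout(lay, dir)
  message(sprintf("layout written to %s (order-2 total %.3f m, %d veins)",
                  dir, lay$order2$total_length, lay$order2$n_veins))
  invisible(lay)
}

#' @rdname run_build
#' @export
run_solve <- function(config = default_config()) {
  params <- .config_params(config)
  s <- config$solver
  lay <- build_vein_layout(
    make_leaf_shape(config$shape$variant),
    spacing = config$shape$spacing_mm / 1000,
    theta = config$veins$theta_deg, mode = config$veins$mode,
    Lv = config$veins$Lv_mm / 1000,
    target_length = config$veins$target_length_m,
    params = params, swap45 = isTRUE(config$veins$swap45)
  )
  fit <- solve_steady(lay, params,
                      solver_settings(tol = s$tol, max_iter = s$max_iter,
                                      C_init = s$C_init,
                                      continuation_steps = s$continuation_steps,
                                      seed = s$seed))
  dir.create(config$output$dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(config$output$dir,
                    sprintf("state_%s_theta%05.2f", config$shape$variant,
                            config$veins$theta_deg))
  write_state(fit, paste0(base, ".csv"), layout = lay)
  report <- c(
    list(config = config,
         avg_p_xyl = area_average(fit, "p_xyl"),
         avg_p_ph = area_average(fit, "p_ph"),
         avg_C = area_average(fit, "C")),
    fit$diagnostics
  )
  jsonlite::write_json(report, paste0(base, "_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' @rdname run_build
#' @export
run_sweep <- function(config = default_config()) {
  params <- .config_params(config)
  s <- config$solver
  shapes <- config$experiment$shapes
  if (identical(shapes, "all")) shapes <- c("wide", "reference", "narrow")
  angles <- .config_angles(config)
  dir.create(config$output$dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (v in shapes) {
    sw <- sweep_vein_angle(
      make_leaf_shape(v), angles = angles, params = params,
      spacing = config$shape$spacing_mm / 1000, mode = config$veins$mode,
      Lv = config$veins$Lv_mm / 1000,
      settings = solver_settings(tol = s$tol, max_iter = s$max_iter,
                                 C_init = s$C_init,
                                 continuation_steps = s$continuation_steps,
                                 seed = s$seed)
    )
    readr::write_csv(sw, file.path(config$output$dir, sprintf("sweep_%s.csv", v)))
    out[[v]] <- sw
  }
  peaks <- purrr::map(out, function(sw) {
    list(peak_theta_p_xyl = find_peak_angle(sw, "avg_p_xyl"),
         variation_p_xyl_pct = variation_metric(sw, "avg_p_xyl"))
  })
  jsonlite::write_json(peaks, file.path(config$output$dir, "sweep_peaks.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
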