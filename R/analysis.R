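#' Leaf-area average of a solved field
#'
#' Arithmetic mean of a state field over all internal (inside-the-leaf)
#' nodes; the petiole boundary node is excluded. This is the whole-leaf
#' transport-efficiency index used throughout.
#'
#' @param state A [solve_steady()] result (or its `nodes` tibble).
#' @param field One of `"p_xyl"`, `"p_ph"`, `"C"` (or any node column).
#' @return A scalar.
#' @export
area_average <- function(state, field = "p_xyl") {
  nodes <- if (inherits(state, "leaf_steady")) state$nodes else state
  pet <- if (inherits(state, "leaf_steady")) state$petiole else NULL
  vals <- nodes[[field]]
  if (is.null(vals)) abort(sprintf("no field '%s' in state", field))
  if (!is.null(pet)) vals <- vals[nodes$node != pet]
  if (!length(vals)) abort("empty node set")
  mean(vals)
}

#' Sweep the second-order vein angle
#'
#' Builds one layout and solves one steady state per requested angle
#' (regenerating the second-order veins under the constant-total-length
#' constraint unless configured otherwise), and collects the area-average
#' indices.
#'
#' @param shape A [make_leaf_shape()] object (or a prebuilt [build_grid()]).
#' @param angles Angles in degrees; default the 13 canonical angles.
#' @param params A [model_params()] object.
#' @param spacing Lattice spacing (m).
#' @param mode Second-order layout mode (see [layout_second_order_veins()]).
#' @param Lv Inter-vein interval for `constant_spacing` mode (m).
#' @param settings [solver_settings()].
#' @param keep_states Keep each full `leaf_steady` in an attribute
#'   `states` (memory-heavy; default FALSE).
#' @return A tibble of class `vein_sweep`, sorted by angle, with columns
#'   `theta`, `avg_p_xyl`, `avg_p_ph`, `avg_C`, `order2_length`, `n_veins`,
#'   `iterations`, `converged`, plus metadata attributes.
#' @export
sweep_vein_angle <- function(shape, angles = paper_angles()$theta,
                             params = model_params(), spacing = 0.002,
                             mode = "constant_total_length", Lv = 0.010,
                             settings = solver_settings(),
                             keep_states = FALSE) {
  grid <- if (inherits(shape, "leaf_grid")) shape else build_grid(shape, spacing)
  states <- list()
  rows <- purrr::map(sort(angles), function(th) {
    lay <- build_vein_layout(grid, theta = th, mode = mode, Lv = Lv,
                             params = params)
    fit <- tryCatch(
      solve_steady(lay, params, settings),
      error = function(e) abort(sprintf("solve failed at theta = %.2f: %s",
                                        th, conditionMessage(e)))
    )
    if (keep_states) states[[as.character(th)]] <<- fit
    tibble(
      theta = th,
      avg_p_xyl = area_average(fit, "p_xyl"),
      avg_p_ph = area_average(fit, "p_ph"),
      avg_C = area_average(fit, "C"),
      order2_length = lay$order2$total_length,
      n_veins = lay$order2$n_veins,
      iterations = fit$diagnostics$iterations,
      converged = fit$diagnostics$converged
    )
  })
  out <- purrr::list_rbind(rows)
  attr(out, "variant") <- grid$shape$variant
  attr(out, "spacing") <- grid$spacing
  attr(out, "mode") <- mode
  if (keep_states) attr(out, "states") <- states
  class(out) <- c("vein_sweep", class(out))
  out
}

#' Angle of maximum response over a sampled sweep
#'
#' Grid argmax of a sweep field (no interpolation, matching the sampled-grid
#' reporting convention); ties break toward the smaller angle.
#'
#' @param table A [sweep_vein_angle()] result (>= 3 rows).
#' @param field Column to maximise, default `"avg_p_xyl"`.
#' @return The peak angle in degrees.
#' @export
find_peak_angle <- function(table, field = "avg_p_xyl") {
  if (nrow(table) < 3) abort("need at least 3 sweep rows")
  if (!all(table$converged)) abort("sweep contains unconverged rows")
  tb <- table[order(table$theta), ]
  tb$theta[which.max(tb[[field]])]
}

#' Degree of variation of a sweep response
#'
#' Percentage spread of a field across a sweep. The default strategy is
#' `100 * (max - min) / |mean|`; `range_over_max` and `range_over_min` are
#' selectable alternatives since no single definition is canonical.
#'
#' @param table A [sweep_vein_angle()] result (>= 2 rows).
#' @param field Column name.
#' @param strategy Normalisation strategy.
#' @return Percentage (scalar).
#' @export
variation_metric <- function(table, field = "avg_p_xyl",
                             strategy = c("range_over_mean", "range_over_max",
                                          "range_over_min")) {
  strategy <- match.arg(strategy)
  v <- table[[field]]
  if (length(v) < 2) abort("need at least 2 rows")
  denom <- switch(strategy,
    range_over_mean = abs(mean(v)),
    range_over_max = abs(max(v)),
    range_over_min = abs(min(v))
  )
  if (denom == 0) abort("zero denominator in variation metric")
  100 * (max(v) - min(v)) / denom
}

#' Xylem-minus-phloem pressure difference map
#'
#' Per-node difference between the xylem hydraulic pressure and the phloem
#' *total* pressure (hydraulic minus osmotic, `p_ph - R T C`). Positive
#' values mark a driving force for water from xylem to phloem; the map is
#' the whole-leaf circulation diagnostic.
#'
#' @param state A [solve_steady()] result.
#' @param params Parameters (defaults to those stored in the state).
#' @return The state's node tibble with an added `p_diff` column (petiole
#'   row included).
#' @export
pressure_difference_map <- function(state, params = state$params) {
  nodes <- state$nodes
  RT <- params$R * params$T
  nodes$p_diff <- nodes$p_xyl - (nodes$p_ph - RT * nodes$C)
  nodes
}
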