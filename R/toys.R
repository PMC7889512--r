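#' Construct a toy network layout directly
#'
#' Builds a minimal layout object accepted by the transport/solver machinery
#' from explicit node and edge tables, bypassing leaf geometry. Used for
#' oracle testing and small worked examples.
#'
#' @param nodes Tibble with `node` (1..n, petiole last), `z` (m) and `area`
#'   (m^2); `x` optional.
#' @param edges Tibble with `from`, `to`, `K_xyl`, `K_ph`, `G_ph`, `length`.
#' @param petiole Node id of the boundary node (default: last node).
#' @param first_node Node id adjacent to the petiole (default: the `to` end
#'   of the petiole's first edge).
#' @param L Nominal domain length (m) used by the loading-gradient option.
#' @return A list of class `vein_layout` (toy flavour).
#' @export
toy_layout <- function(nodes, edges, petiole = max(nodes$node),
                       first_node = NULL, L = 0.1) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!"x" %in% names(nodes)) nodes$x <- 0
  if (!"order" %in% names(edges)) edges$order <- NA_integer_
  if (is.null(first_node)) {
    pe <- edges[edges$from == petiole | edges$to == petiole, ][1, ]
    first_node <- if (pe$from == petiole) pe$to else pe$from
  }
  structure(
    list(
      nodes = nodes, edges = edges, petiole = petiole,
      first_node = first_node, theta = NA_real_, mode = "toy",
      spacing = NA_real_, shape = list(variant = "toy", length = L),
      order2 = NULL
    ),
    class = "vein_layout"
  )
}

#' Toy chain network
#'
#' A uniform chain of `n` nodes hanging off the petiole, matching the
#' geometry of [xylem_chain_closed_form()].
#'
#' @param n Number of internal nodes.
#' @param K_edge Xylem conductance of every edge (mmol s^-1 MPa^-1).
#' @param a Per-node area (m^2).
#' @param phloem_factor Ratio of phloem to xylem conductance.
#' @param G Diffusive sucrose conductance per edge (m^3 s^-1).
#' @return A toy `vein_layout`.
#' @export
toy_chain <- function(n, K_edge = 5, a = 4e-6, phloem_factor = 0.03, G = 4e-12) {
  pet <- n + 1L
  nodes <- tibble(
    node = seq_len(pet),
    z = c(seq_len(n) * 0.01, 0),
    area = c(rep(a, n), 0)
  )
  edges <- tibble(
    from = c(pet, seq_len(n - 1L)),
    to = seq_len(n),
    K_xyl = K_edge, K_ph = phloem_factor * K_edge, G_ph = G,
    length = 0.01
  )
  toy_layout(nodes, edges, petiole = pet, first_node = 1L, L = n * 0.01)
}

#' Random toy network
#'
#' A random connected network (spanning tree plus extra edges) with
#' randomised conductances and areas, for property-based solver testing.
#'
#' @param n Number of internal nodes (the petiole is added on top).
#' @param extra Number of extra non-tree edges.
#' @return A toy `vein_layout`.
#' @export
random_toy <- function(n = 8L, extra = 3L) {
  pet <- n + 1L
  nodes <- tibble(
    node = seq_len(pet),
    z = c(runif(n, 0.005, 0.095), 0),
    area = c(4e-6 * runif(n, 0.5, 2), 0)
  )
  parent <- c(pet, vapply(2:n, function(k) sample.int(k - 1L, 1L), integer(1)))
  ef <- parent
  et <- seq_len(n)
  if (extra > 0L && n >= 3L) {
    for (k in seq_len(extra)) {
      ab <- sample.int(n, 2L)
      ef <- c(ef, ab[1])
      et <- c(et, ab[2])
    }
  }
  keep <- !duplicated(paste(pmin(ef, et), pmax(ef, et))) & ef != et
  ef <- ef[keep]
  et <- et[keep]
  K <- 10^runif(length(ef), -2, 0.5)
  edges <- tibble(
    from = ef, to = et,
    K_xyl = K, K_ph = 0.03 * K,
    G_ph = 10^runif(length(ef), -16, -14),
    length = runif(length(ef), 0.002, 0.02)
  )
  toy_layout(nodes, edges, petiole = pet, first_node = 1L)
}
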