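# Flux primitives, residual assembly and conservation structure.

test_that("flux primitives compute the documented forms", {
  p <- model_params()
  RT <- p$R * p$T
  # plain Darcy
  expect_equal(xylem_edge_flux(5, 0, -1.6e-6), 5 * -1.6e-6)
  # with the default lateral reflection coefficient 0 the phloem flux is Darcy
  expect_equal(phloem_edge_flux(0.15, 0.1, 0.3, 50, 250, p), 0.15 * 0.2)
  # a nonzero reflection coefficient brings in the osmotic term
  p_s <- model_params(sigma_lateral = 1)
  expect_equal(phloem_edge_flux(0.15, 0.1, 0.3, 50, 250, p_s),
               0.15 * (0.2 - RT * 200))
  # cross conduit: osmotic pull of the phloem sap draws xylem water
  expect_equal(cross_flux(0.5, 0.2, 100, 0, p), 0.5 * (0.2 - RT * 100))
  expect_lt(cross_flux(0.5, 0.2, 100, 0, p), 0)
  # forcing terms
  expect_equal(transpiration_flux(-2, 4e-6), -8e-6)
  expect_equal(sucrose_loading(2.78e-7, 4e-6), 2.78e-7 * 4e-6)
})

test_that("sucrose edge flux: literal carries the centre node, upwind the donor", {
  p <- model_params()
  G <- 4e-12
  # literal: convective factor is always C_ij regardless of flow direction
  expect_equal(sucrose_edge_flux(2, 10, 30, G, p, scheme = "literal"),
               p$v_mu * 2 * 10 + G * 20)
  expect_equal(sucrose_edge_flux(-2, 10, 30, G, p, scheme = "literal"),
               p$v_mu * -2 * 10 + G * 20)
  # upwind: influx (F >= 0) carries the neighbour, efflux the centre node
  expect_equal(sucrose_edge_flux(2, 10, 30, G, p, scheme = "upwind"),
               p$v_mu * 2 * 30 + G * 20)
  expect_equal(sucrose_edge_flux(-2, 10, 30, G, p, scheme = "upwind"),
               p$v_mu * -2 * 10 + G * 20)
})

test_that("water fluxes are antisymmetric under edge reversal; upwind sucrose too", {
  p <- model_params()
  set.seed(7)
  K <- runif(50, 0.01, 5)
  pa <- runif(50, -1, 1); pb <- runif(50, -1, 1)
  Ca <- runif(50, 0, 300); Cb <- runif(50, 0, 300)
  expect_equal(xylem_edge_flux(K, pa, pb), -xylem_edge_flux(K, pb, pa))
  expect_equal(phloem_edge_flux(K, pa, pb, Ca, Cb, p),
               -phloem_edge_flux(K, pb, pa, Cb, Ca, p))
  Fab <- phloem_edge_flux(K, pa, pb, Ca, Cb, p)
  G <- 10^runif(50, -14, -11)
  expect_equal(sucrose_edge_flux(Fab, Ca, Cb, G, p, scheme = "upwind"),
               -sucrose_edge_flux(-Fab, Cb, Ca, G, p, scheme = "upwind"))
  # literal is NOT pairwise antisymmetric (the documented conservation gap)
  s_lit <- sucrose_edge_flux(Fab, Ca, Cb, G, p, scheme = "literal") +
    sucrose_edge_flux(-Fab, Cb, Ca, G, p, scheme = "literal")
  expect_gt(max(abs(s_lit)), 0)
  expect_equal(s_lit, p$v_mu * Fab * (Ca - Cb))
})

test_that("residual at a flow-free uniform state reduces to the forcings", {
  lay <- toy_chain(4)
  p <- model_params()
  n <- nrow(lay$nodes)
  st <- list(p_xyl = rep(0, n), p_ph = rep(0, n), C = rep(0, n))
  r <- assemble_residual(lay, p, st)
  a <- lay$nodes$area
  # no pressure or concentration differences: xylem rows = E*a, phloem rows 0,
  # sucrose rows = Lambda*a; petiole rows = BC residuals
  expect_equal(r$r_xyl[1:4], p$E * a[1:4])
  expect_equal(r$r_ph[1:4], rep(0, 4))
  expect_equal(r$r_suc[1:4], p$Lambda * a[1:4])
  expect_equal(r$r_xyl[5], -p$petiole_p_xyl)
  expect_equal(r$r_ph[5], -p$petiole_p_ph)
  expect_equal(r$r_suc[5], 0)
})

test_that("the two-node chain closed form zeroes the xylem residual exactly", {
  lay <- toy_chain(1, K_edge = 5, a = 4e-6)
  p <- model_params(K_c = 0, E = -2)
  # E * a = -8e-6 and K = 5 give p_1 = p_0 - 1.6e-6
  p1 <- xylem_chain_closed_form(1, 5, -2, 4e-6, p$petiole_p_xyl)
  expect_equal(p1, p$petiole_p_xyl - 1.6e-6)
  st <- list(p_xyl = c(p1, p$petiole_p_xyl),
             p_ph = rep(p$petiole_p_ph, 2), C = rep(100, 2))
  r <- assemble_residual(lay, p, st)
  expect_lt(abs(r$r_xyl[1]), 1e-18)
})

test_that("total transpiration equals E times the blade area", {
  g <- build_grid(make_leaf_shape("reference"), 0.002)
  p <- model_params()
  tot <- sum(transpiration_flux(p$E, g$nodes$area))
  expect_equal(tot, p$E * sum(g$nodes$area))
  # and the closed-area invariant makes that E * leaf area to within 1%
  expect_lt(abs(tot - (-2 * 73.35e-4)) / (2 * 73.35e-4), 0.01)
})

test_that("gradient loading preserves the leaf-area-weighted mean rate", {
  g <- build_grid(make_leaf_shape("reference"), 0.002)
  p <- model_params(loading = "gradient")
  lr <- loading_rates(p, g$nodes, g$shape$length)
  # linear profile: 1.5x the mean at the base to 0.5x at the tip
  expect_equal(lr, p$Lambda * (1.5 - g$nodes$z / g$shape$length))
  tot <- sum(lr * g$nodes$area)
  expect_lt(abs(tot - p$Lambda * sum(g$nodes$area)) / (p$Lambda * sum(g$nodes$area)),
            1e-10)
  # uniform loading is flat
  lu <- loading_rates(model_params(), g$nodes, g$shape$length)
  expect_equal(lu, rep(2.78e-7, nrow(g$nodes)))
})

test_that("balance closures hold at convergence; upwind conserves sucrose exactly", {
  lay <- build_vein_layout(make_leaf_shape("reference"), spacing = 0.004,
                           theta = 45)
  fit_l <- solve_steady(lay, model_params(sucrose_scheme = "literal"))
  fit_u <- solve_steady(lay, model_params(sucrose_scheme = "upwind"))
  for (fit in list(fit_l, fit_u)) {
    d <- fit$diagnostics
    # water: petiole inflow balances transpiration plus cross transfer,
    # and the phloem side returns the cross transfer through the petiole
    expect_lt(abs(d$xylem_closure_gap), 1e-10)
    expect_lt(abs(d$phloem_closure_gap), 1e-10)
    # cross transfer moves water xylem -> phloem in steady operation
    expect_gt(d$total_cross_to_phloem, 0)
    expect_lt(d$total_transpiration, 0)
  }
  # sucrose: exact closure under upwind, finite reported gap under literal
  expect_lt(abs(fit_u$diagnostics$sucrose_conservation_gap),
            1e-12 * fit_u$diagnostics$total_loading)
  expect_gt(abs(fit_l$diagnostics$sucrose_conservation_gap),
            1e-6 * fit_l$diagnostics$total_loading)
  expect_lt(abs(fit_l$diagnostics$sucrose_conservation_gap),
            fit_l$diagnostics$total_loading)
})
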