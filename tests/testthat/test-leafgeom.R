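# Leaf outlines, node lattice, vein rasterization and conductance assignment.

test_that("leaf outlines hit the common blade area and printed dimensions", {
  target <- 73.35e-4
  dims <- list(reference = c(0.160, 0.0647),
               wide = c(0.128, 0.0809),
               narrow = c(0.192, 0.0539))
  for (v in names(dims)) {
    sh <- make_leaf_shape(v)
    expect_equal(sh$length, dims[[v]][1])
    expect_equal(sh$width, dims[[v]][2])
    # independent quadrature of the outline area
    area <- stats::integrate(function(z) 2 * sh$half_width(z), 0, sh$length,
                             rel.tol = 1e-10)$value
    expect_lt(abs(area - target) / target, 0.005)
    # widest point is mid-blade at the full half-width
    expect_equal(sh$half_width(sh$length / 2), sh$width / 2, tolerance = 1e-12)
    expect_equal(sh$half_width(0), 0)
    expect_equal(sh$half_width(sh$length), 0, tolerance = 1e-12)
  }
  # shared area but different exponents
  qs <- vapply(names(dims), function(v) make_leaf_shape(v)$exponent, numeric(1))
  expect_true(all(qs > 0))
  expect_gt(max(qs) - min(qs), 1e-3)
})

test_that("lattice nodal areas close the blade area and the lattice is sane", {
  for (v in c("reference", "wide", "narrow")) {
    sh <- make_leaf_shape(v)
    g <- build_grid(sh, 0.002)
    tot <- sum(g$nodes$area)
    expect_lt(abs(tot - sh$area) / sh$area, 0.01)
    expect_true(all(g$nodes$area > 0))
    # all nodes truly inside the outline
    expect_true(all(abs(g$nodes$x) <= sh$half_width(g$nodes$z) + 1e-12))
    # petiole is the external node appended after the inside nodes
    expect_identical(g$petiole, nrow(g$nodes) + 1L)
    expect_identical(g$nodes$i[g$nodes$node == g$first_node], 1L)
    expect_identical(g$nodes$j[g$nodes$node == g$first_node], 0L)
    # point membership agrees between the closure and the node table
    expect_true(all(g$inside(g$nodes$i, g$nodes$j)))
    expect_false(g$inside(1L, g$jmax + 5L))
  }
  # reference at the default spacing also matches the documented node-count scale
  g <- build_grid(make_leaf_shape("reference"), 0.002)
  expect_gt(nrow(g$nodes), 1500)
  expect_lt(nrow(g$nodes), 2200)
})

test_that("too-coarse spacings are rejected", {
  expect_error(build_grid(make_leaf_shape("narrow"), 0.02), "too coarse")
  expect_error(build_grid(make_leaf_shape("reference"), 0.0647 / 4), "too coarse")
})

test_that("angle_ratio resolves the canonical vocabulary and rejects others", {
  can <- paper_angles()
  expect_identical(nrow(can), 13L)
  for (k in seq_len(nrow(can))) {
    r <- angle_ratio(can$theta[k])
    expect_identical(r$p, can$p[k])
    expect_identical(r$q, can$q[k])
    # printed angle agrees with the exact lattice angle to printing precision
    expect_lt(abs(r$theta_exact - can$theta[k]), 0.05)
  }
  expect_identical(angle_ratio(45)$p, 1L)
  expect_error(angle_ratio(33), "not grid-compatible")
  expect_error(angle_ratio(-1), "in \\[0, 90\\)")
  expect_error(angle_ratio(90), "in \\[0, 90\\)")
})

test_that("staircase rasterization realises each angle exactly", {
  g <- build_grid(make_leaf_shape("reference"), 0.002)
  i_mid <- as.integer(round(g$ni / 2))
  can <- paper_angles()
  for (k in seq_len(nrow(can))) {
    p <- can$p[k]; q <- can$q[k]
    e <- rasterize_vein(g, i_mid, +1, can$theta[k])
    np <- if (p == 0L) 1L else max(p, q) # lattice steps per period
    expect_gte(nrow(e), np)
    # net displacement over one full period is exactly (p longitudinal,
    # q lateral) lattice units
    expect_identical(e$i2[np] - i_mid, p)
    expect_identical(e$j2[np], q)
    # all endpoints stay inside the outline
    expect_true(all(g$inside(e$i2, e$j2)))
    # edge lengths are h or h*sqrt(2) according to the step type
    expect_equal(e$length, ifelse(e$diag, g$spacing * sqrt(2), g$spacing))
  }
  # 45 degrees is all diagonal steps, 0 degrees all lateral
  e45 <- rasterize_vein(g, i_mid, +1, 45)
  expect_true(all(e45$diag))
  e0 <- rasterize_vein(g, i_mid, +1, 0)
  expect_true(all(!e0$diag))
  expect_true(all(e0$i2 == i_mid))
  # left side mirrors the right side
  eL <- rasterize_vein(g, i_mid, -1, 45)
  expect_identical(eL$j2, -e45$j2)
  expect_identical(eL$i2, e45$i2)
})

test_that("constant-total-length layouts hit the target for all shapes and angles", {
  for (v in c("reference", "wide", "narrow")) {
    g <- build_grid(make_leaf_shape(v), 0.002)
    for (th in c(0, 45, 75.96)) {
      o2 <- layout_second_order_veins(g, th)
      expect_lt(abs(o2$total_length - 0.74), 0.01)
      expect_identical(o2$n_veins, 2L * length(o2$attach_rows))
      # attachment rows are distinct and on the lattice (the length
      # refinement may shift individual rows, including the first)
      expect_false(anyDuplicated(o2$attach_rows) > 0)
      expect_true(all(o2$attach_rows >= 1L & o2$attach_rows <= g$ni))
    }
  }
})

test_that("constant-spacing layouts float the total with the angle", {
  g <- build_grid(make_leaf_shape("reference"), 0.002)
  o0 <- layout_second_order_veins(g, 0, mode = "constant_spacing", Lv = 0.010)
  o76 <- layout_second_order_veins(g, 75.96, mode = "constant_spacing", Lv = 0.010)
  expect_equal(o0$Lv1, 0.010)
  expect_equal(o0$Lv2, 0.010)
  # unrefined mode: the first attachment sits at the 5 mm row
  expect_identical(min(o0$attach_rows),
                   max(1L, as.integer(round(0.005 / g$spacing))))
  # steeper veins run much longer on the same attachment grid
  expect_gt(o76$total_length, o0$total_length)
})

test_that("background lattice orders follow the 6-line pattern and cover the lattice", {
  g <- build_grid(make_leaf_shape("reference"), 0.002)
  bg <- layout_higher_order_veins(g)
  # coverage: one edge per adjacent inside pair
  n_lat <- sum(g$inside(g$nodes$i, g$nodes$j + 1L))
  n_lon <- sum(g$inside(g$nodes$i + 1L, g$nodes$j))
  expect_identical(nrow(bg), n_lat + n_lon)
  # the main vein occupies the whole symmetry axis
  mv <- bg[bg$j1 == 0L & bg$j2 == 0L, ]
  expect_true(all(mv$order == 1L))
  mvn <- g$nodes$i[g$nodes$j == 0L]
  expect_identical(nrow(mv), sum(g$inside(mvn + 1L, rep(0L, length(mvn)))))
  # order pattern on lateral lines: row line index i-1, every 6th is order 3,
  # remaining even lines order 4, odd lines order 5
  lat <- bg[bg$i1 == bg$i2, ]
  idx <- lat$i1 - 1L
  expect_true(all(lat$order[idx %% 6L == 0L] == 3L))
  expect_true(all(lat$order[idx %% 6L != 0L & idx %% 2L == 0L] == 4L))
  expect_true(all(lat$order[idx %% 2L == 1L] == 5L))
  # swap45 exchanges orders 4 and 5 only
  bg_s <- layout_higher_order_veins(g, swap45 = TRUE)
  expect_identical(bg_s$order[bg$order == 4L], rep(5L, sum(bg$order == 4L)))
  expect_identical(bg_s$order[bg$order == 5L], rep(4L, sum(bg$order == 5L)))
  expect_identical(bg_s$order[bg$order <= 3L], bg$order[bg$order <= 3L])
})

test_that("full layout merges orders, is mirror symmetric, and wires the petiole", {
  lay <- build_vein_layout(make_leaf_shape("reference"), spacing = 0.002,
                           theta = 45)
  e <- lay$edges
  # lowest order wins: the symmetry axis stays order 1 everywhere
  expect_true(all(e$order[e$j1 == 0L & e$j2 == 0L] == 1L))
  # no duplicated edges
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_false(any(duplicated(key)))
  # petiole conduit: 5 mm, order 1, external node to (1, 0)
  pe <- e[e$from == lay$petiole, ]
  expect_identical(nrow(pe), 1L)
  expect_equal(pe$length, 0.005)
  expect_identical(pe$order, 1L)
  expect_identical(pe$to, lay$first_node)
  # mirror symmetry of the edge set under j -> -j
  k1 <- paste(pmin(paste(e$i1, e$j1), paste(e$i2, e$j2)),
              pmax(paste(e$i1, e$j1), paste(e$i2, e$j2)), e$order)
  k2 <- paste(pmin(paste(e$i1, -e$j1), paste(e$i2, -e$j2)),
              pmax(paste(e$i1, -e$j1), paste(e$i2, -e$j2)), e$order)
  expect_setequal(k1, k2)
  # order-2 total length carried through
  expect_lt(abs(lay$order2$total_length - 0.74), 0.01)
})

test_that("conductances follow conductivity / length with the documented table", {
  lay <- build_vein_layout(make_leaf_shape("reference"), spacing = 0.002,
                           theta = 45)
  e <- lay$edges
  k <- default_conductivities()
  expect_equal(k$conductivity, c(1.00e-2, 5.00e-4, 6.00e-5, 4.00e-5, 4.00e-6))
  expect_equal(k$diameter, c(15.50e-6, 11.30e-6, 7.50e-6, 7.20e-6, 4.34e-6))
  expect_equal(e$K_xyl, k$conductivity[e$order] / e$length)
  expect_equal(e$K_ph, 0.03 * e$K_xyl)
  expect_equal(e$G_ph, 5.22e-10 * pi * k$diameter[e$order]^2 / 4 / e$length)
  # spot value: a 2 mm order-1 edge has K_xyl = 1e-2 / 2e-3 = 5
  o1 <- e[e$order == 1L & abs(e$length - 0.002) < 1e-12, ]
  expect_true(all(abs(o1$K_xyl - 5) < 1e-12))
  # order-2 multiplier helper
  expect_equal(order2_multiplier(5)[2], 2.5e-3)
  expect_equal(order2_multiplier(1 / 5)[2], 1e-4)
  expect_equal(order2_multiplier(5)[-2], k$conductivity[-2])
})
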