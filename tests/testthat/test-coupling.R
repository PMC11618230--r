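test_that("re-solve trigger fires exactly at the residual budget", {
  pp <- porosity_params(pi_coeff = 2 * 1030, Cfb0 = 1, n_hill = 4)
  fp <- fluid_properties(rho = 1030)
  u <- rep(1e-3, 10)
  # unchanged field never triggers
  tr0 <- resolve_trigger(rep(0.3, 10), rep(0.3, 10), u, pp, fp, dt = 1,
                         eps2 = 1e-3)
  expect_false(tr0$trigger)
  expect_equal(tr0$deltaR, 0)
  # delta-phi = 0.5 with pi/rho = 2, |u| = 1e-3, dt = 1 -> deltaR = 1e-3
  tr1 <- resolve_trigger(rep(pp$Cfb0, 10), rep(0, 10), u, pp, fp, dt = 1,
                         eps2 = 1e-3)
  expect_equal(tr1$deltaR, 1e-3, tolerance = 1e-12)
  expect_true(tr1$trigger)
  # a zero budget triggers on any change
  expect_true(resolve_trigger(rep(1e-9, 10), rep(0, 10), u, pp, fp, 1, 0)$trigger)
})

test_that("zeroed fibrin pathways never re-trigger the flow", {
  sc <- tiny_tube_scenario(end_time = 0.03)
  sc$params$reaction <- reaction_params(Kwt = 0, Kth = 0, Kss = 0, Kwa = 0,
                                        Kb = 0, r0 = sc$params$reaction$r0)
  sc$cfg$transport_time_cap <- 0.01
  st <- run_coupled(sc$mesh, sc$ib, sc$params, sc$cfg, wires = sc$wires)
  expect_equal(st$n_flow_solves, 1L)
  expect_equal(max(st$C[, 6]), 0)
  expect_false(any(st$metrics$resolved))
})

test_that("checkpoint restart reproduces the uninterrupted run exactly", {
  dir <- withr::local_tempdir()
  sc <- tiny_tube_scenario(end_time = 0.06)
  sc$cfg$transport_time_cap <- 0.015   # force several coupled steps
  st_full <- run_coupled(sc$mesh, sc$ib, sc$params, sc$cfg, wires = sc$wires)
  expect_gt(st_full$coupled_step, 2L)

  sc$cfg$checkpoint_dir <- dir
  st_a <- run_coupled(sc$mesh, sc$ib, sc$params, sc$cfg, wires = sc$wires)
  cks <- list.files(dir, full.names = TRUE)
  expect_gt(length(cks), 0L)
  mid <- cks[ceiling(length(cks) / 2)]
  sc$cfg$checkpoint_dir <- NULL
  st_b <- run_coupled(sc$mesh, sc$ib, sc$params, sc$cfg, wires = sc$wires,
                      restart = mid)
  expect_equal(st_b$global_time, st_full$global_time, tolerance = 1e-15)
  denom <- max(abs(st_full$C))
  expect_lt(max(abs(st_b$C - st_full$C)) / denom, 1e-12)
  expect_lt(max(abs(st_b$flow$u - st_full$flow$u)), 1e-12)
})

test_that("uniform axial flow through the tube midplane recovers the flow rate", {
  m <- generate_tube_mesh(3e-4, 1.5e-3, 4e-5)
  u <- matrix(0, nrow(m$nodes), 3); u[, 1] <- 0.02
  plane <- list(center = c(7.5e-4, 0, 0), normal = c(1, 0, 0), radius = 1.5e-4)
  Q <- aneurysm_inflow(m, u, plane)
  expect_equal(Q, 0.02 * pi * 1.5e-4^2, tolerance = 0.02 * 0.02 * pi * 1.5e-4^2)
  expect_equal(aneurysm_inflow(m, u * 0, plane), 0)
})

test_that("covered fraction is zero without bounded fibrin", {
  tr <- tube_run("tube90")
  C0 <- tr$st$C * 0
  expect_equal(covered_cell_fraction(tr$sc$mesh, C0, tr$sc$wires,
                                     tr$sc$params$porosity), 0)
})
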