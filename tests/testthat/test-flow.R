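test_that("Darcy force follows the Hill switch of bounded fibrin", {
  pp <- porosity_params(pi_coeff = 1e6, Cfb0 = 0.05, n_hill = 2)
  u <- c(0.01, 0, -0.02)
  expect_equal(darcy_force(0, u, pp), c(0, 0, 0))
  expect_equal(darcy_force(pp$Cfb0, u, pp), -0.5 * 1e6 * u)
  expect_equal(darcy_force(2 * pp$Cfb0, u, pp), -0.8 * 1e6 * u)
  # antiparallel and saturating
  F <- darcy_force(1e4 * pp$Cfb0, u, pp)
  expect_equal(F, -1e6 * u, tolerance = 1e-6)
})

test_that("shear stress of canonical velocity fields is exact", {
  m <- generate_box_mesh(1e-3, 5e-4, 5e-4, 4, 3, 3)
  fp <- fluid_properties()
  u_const <- matrix(rep(c(0.01, -0.003, 0.002), each = nrow(m$nodes)), ncol = 3)
  expect_lt(max(shear_stress(u_const, m, fp)), 1e-12)
  gdot <- 120
  u_shear <- cbind(gdot * m$nodes[, 2], 0, 0)
  tau <- shear_stress(u_shear, m, fp)
  expect_equal(tau, rep(fp$mu * gdot, length(tau)), tolerance = 1e-10)
})

test_that("zero inflow produces a quiescent field", {
  m <- generate_tube_mesh(3e-4, 1.5e-3, 5e-5)
  fs <- solve_steady(m, NULL, 0, flow_bc(mean_velocity = 0),
                     fluid_properties(), porosity_params(), flow_config())
  expect_lt(max(abs(fs$u)), 1e-12)
  expect_lt(diff(range(fs$p)), 1e-8)
})

test_that("residual split isolates the porosity contribution", {
  pc <- poiseuille_case()
  fp <- pc$fp
  pp0 <- porosity_params(pi_coeff = 1e6)
  rs0 <- flow_residual_split(pc$flow, pc$mesh, fp, pp0, Cfb = 0)
  expect_equal(max(abs(rs0$R2)), 0)
  Cfb <- rep(2 * pp0$Cfb0, nrow(pc$mesh$tets))
  rs1 <- flow_residual_split(pc$flow, pc$mesh, fp, pp0, Cfb)
  pp2 <- porosity_params(pi_coeff = 2e6)
  rs2 <- flow_residual_split(pc$flow, pc$mesh, fp, pp2, Cfb)
  expect_equal(rs2$R2, 2 * rs1$R2, tolerance = 1e-12)
  expect_gt(max(abs(rs1$R2)), 0)
})

test_that("flow-rate BCs reproduce the requested flux exactly", {
  m <- generate_tube_mesh(3e-4, 1.5e-3, 4e-5)
  Q <- 1.06e-9   # 1.5 cm/s on the analytic disc
  fs <- solve_steady(m, NULL, 0, flow_bc(flow_rate = Q),
                     fluid_properties(), porosity_params(), flow_config())
  qin <- -boundary_flux(m, fs$u, "inlet")
  expect_equal(qin, Q, tolerance = 1e-9)
})

test_that("mass balance holds with immersed wires in the tube", {
  # native resolution: wires resolved by the mesh (h ~ wire diameter)
  sc <- build_scenario("tube90", h_scale = 1.0)
  flow <- solve_steady(sc$mesh, sc$ib, 0, sc$params$bc, sc$params$fluid,
                       sc$params$porosity, flow_config())
  qin <- -boundary_flux(sc$mesh, flow$u, "inlet")
  qout <- boundary_flux(sc$mesh, flow$u, "outlet")
  expect_lt(abs(qin - qout) / qin, 1e-2)
})

test_that("pressure drop grows with uniform clot density", {
  m <- generate_tube_mesh(3e-4, 1.5e-3, 5e-5)
  fp <- fluid_properties(); pp <- porosity_params(pi_coeff = 1e6)
  bc <- flow_bc(mean_velocity = 0.015)
  dps <- vapply(c(0, 0.5, 1, 2) * pp$Cfb0, function(cfb) {
    fs <- solve_steady(m, NULL, rep(cfb, nrow(m$tets)), bc, fp, pp,
                       flow_config())
    mean(fs$p[m$node_tag == 1L]) - mean(fs$p[m$node_tag == 2L])
  }, 1)
  expect_true(all(diff(dps) > 0))
})
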