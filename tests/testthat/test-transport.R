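test_that("closed box conserves species mass to machine precision per step", {
  bt <- box_transport(ux = 0)
  set.seed(7)
  C <- matrix(runif(nrow(bt$mesh$tets) * 6), ncol = 6)
  D <- species_diffusivities(5e-9)
  tot0 <- colSums(C * bt$mesh$V)
  s <- transport_step(bt$tp, C, D, reaction_params(), inlet_concentrations(),
                      dt = 1e-4, react = FALSE)
  tot1 <- colSums(s$C * bt$mesh$V)
  expect_lt(max(abs(tot1 - tot0) / tot0), 1e-12)
})

test_that("uniform concentration in uniform flow stays uniform", {
  bt <- box_transport()
  C <- matrix(1, nrow(bt$mesh$tets), 6)
  inl <- stats::setNames(rep(1, 6), SPECIES)
  s <- transport_step(bt$tp, C, species_diffusivities(), reaction_params(),
                      inl, dt = 5e-4, react = FALSE)
  expect_lt(max(abs(s$C[, 1:5] - 1)), 1e-13)
})

test_that("upwind fluxes take the upstream value and are antisymmetric", {
  bt <- box_transport()
  ne <- nrow(bt$mesh$tets)
  C <- matrix(seq_len(ne) / ne, ne, 6)
  D <- species_diffusivities(0)
  fl <- face_fluxes(bt$tp, C, D, stats::setNames(rep(0, 6), SPECIES))
  ii <- bt$tp$flux_interior
  up <- ifelse(bt$tp$un_A[ii] >= 0, bt$tp$k1[ii], bt$tp$k2[ii])
  expect_equal(fl$conv[ii, 1], bt$tp$un_A[ii] * C[up, 1], tolerance = 1e-14)
  # wall faces carry nothing
  wall <- which(is.na(bt$tp$k2))
  wall <- setdiff(wall, c(bt$tp$inlet, bt$tp$outlet))
  expect_equal(max(abs(fl$conv[wall, ])), 0)
  expect_equal(max(abs(fl$diff[wall, ])), 0)
  # bounded species is never transported
  expect_equal(max(abs(fl$conv[, 6])), 0)
})

test_that("zero inlet concentrations give zero boundary influx", {
  bt <- box_transport()
  C <- matrix(0, nrow(bt$mesh$tets), 6)
  fl <- face_fluxes(bt$tp, C, species_diffusivities(),
                    stats::setNames(rep(0, 6), SPECIES))
  expect_equal(sum(abs(fl$conv[bt$tp$inlet, ])), 0)
})

test_that("advected step profile stays monotone with non-increasing variation", {
  bt <- box_transport(nx = 40, ny = 3, nz = 3)
  ne <- nrow(bt$mesh$tets)
  C <- matrix(0, ne, 6)
  C[bt$mesh$centroid[, 1] < 5e-4, 4] <- 1
  inl <- stats::setNames(c(0, 0, 0, 1, 0, 0), SPECIES)
  D <- species_diffusivities(0)
  cfg <- transport_config(courant = 0.5)
  # total variation of the 1D (streamwise) profile: layer means along x
  layer <- as.integer(round(bt$mesh$centroid[, 1] / (2e-3 / 40) + 0.5))
  TV <- function(C) {
    prof <- tapply(C[, 4], layer, mean)
    sum(abs(diff(prof)))
  }
  tv <- TV(C)
  for (i in 1:60) {
    dt <- stable_dt(bt$tp, C, D, reaction_params(), cfg)
    s <- transport_step(bt$tp, C, D, reaction_params(), inl, dt, cfg,
                        react = FALSE)
    C <- s$C
    expect_lte(max(C[, 4]), 1 + 1e-12)
    expect_gte(min(C[, 4]), -1e-15)
    tv_new <- TV(C)
    expect_lte(tv_new, tv + 1e-12)
    tv <- tv_new
  }
})

test_that("steady advection balances outlet flux against inlet flux", {
  bt <- box_transport(nx = 20, ny = 3, nz = 3)
  ne <- nrow(bt$mesh$tets)
  C <- matrix(0, ne, 6)
  inl <- stats::setNames(c(1.4, 2.41, 0, 7, 0, 0), SPECIES)
  D <- species_diffusivities(0)
  cfg <- transport_config(courant = 0.8)
  for (i in 1:600) {
    dt <- stable_dt(bt$tp, C, D, reaction_params(), cfg)
    C <- transport_step(bt$tp, C, D, reaction_params(), inl, dt, cfg,
                        react = FALSE)$C
  }
  fl <- face_fluxes(bt$tp, C, D, inl)
  influx <- -sum(fl$conv[bt$tp$inlet, 4])
  outflux <- sum(fl$conv[bt$tp$outlet, 4])
  expect_lt(abs(influx - outflux) / influx, 1e-6)
})

test_that("TVD reconstruction reduces the L1 advection error", {
  m <- generate_box_mesh(2e-3, 3e-4, 3e-4, 40, 3, 3)
  u0 <- matrix(0, nrow(m$nodes), 3); u0[, 1] <- 0.01
  D <- species_diffusivities(0)
  inl <- stats::setNames(rep(0, 6), SPECIES)
  prof <- function(x) exp(-((x - 6e-4) / 2e-4)^2)
  l1 <- function(scheme) {
    cfg <- transport_config(courant = 0.4, scheme = scheme)
    tp <- transport_operators(m, NULL, cfg)
    tp <- transport_set_flow(tp, u = u0, tau_elem = 0)
    C <- matrix(0, nrow(m$tets), 6)
    C[, 4] <- prof(m$centroid[, 1])
    t <- 0; tgt <- 8e-4 / 0.01
    while (t < tgt - 1e-12) {
      dt <- min(stable_dt(tp, C, D, reaction_params(), cfg), tgt - t)
      C <- transport_step(tp, C, D, reaction_params(), inl, dt, cfg,
                          react = FALSE)$C
      t <- t + dt
    }
    sum(abs(C[, 4] - prof(m$centroid[, 1] - 8e-4)) * m$V)
  }
  expect_lt(l1("tvd"), l1("upwind1"))
})

test_that("timestep bounds follow convection, diffusion and divergence limits", {
  bt <- box_transport(ux = 0.01)
  C <- matrix(1, nrow(bt$mesh$tets), 6)
  p <- reaction_params(Kwt = 0, Kat = 0, Kth = 0, Kss = 0, Kwa = 0, Kb = 0)
  cfg <- transport_config(courant = 0.5)
  dt1 <- stable_dt(bt$tp, C, species_diffusivities(0), p, cfg)
  hmin <- min(bt$mesh$h)
  # never looser than the convective bound, never tighter than the rigorous
  # per-element outflux bound
  expect_lte(dt1, 0.5 * hmin / 0.01 + 1e-15)
  expect_equal(dt1, 0.5 * min(hmin / 0.01, min(bt$mesh$V / bt$tp$outflux)),
               tolerance = 1e-9)
  # a large diffusivity takes over the bound
  Dbig <- species_diffusivities(1e-5)
  dt2 <- stable_dt(bt$tp, C, Dbig, p, cfg)
  expect_equal(dt2, 0.5 * min(bt$mesh$h^2) / (2 * 1e-5), tolerance = 1e-6)
  # no constraints at all -> the configured cap
  bt0 <- box_transport(ux = 0)
  cfg_cap <- transport_config(courant = 0.5, dt_cap = 0.25)
  dt3 <- stable_dt(bt0$tp, C * 0, species_diffusivities(0), p, cfg_cap)
  expect_equal(dt3, 0.5 * 0.25)
})

test_that("bounded-fibrin neighbourhood averaging matches brute force", {
  m <- generate_box_mesh(6e-4, 3e-4, 3e-4, 4, 2, 2)
  fl <- 1.6e-4
  set.seed(11)
  Cfb <- runif(nrow(m$tets))
  avg <- bounded_neighbor_average(Cfb, m, fl)
  cc <- m$centroid
  brute <- vapply(seq_len(nrow(cc)), function(k) {
    d <- sqrt(colSums((t(cc) - cc[k, ])^2))
    mean(Cfb[d <= fl])
  }, 1)
  expect_equal(avg, brute, tolerance = 1e-12)
  # uniform field is a fixed point; zero radius is the identity
  expect_equal(bounded_neighbor_average(rep(2, nrow(m$tets)), m, fl),
               rep(2, nrow(m$tets)), tolerance = 1e-12)
  expect_equal(bounded_neighbor_average(Cfb, m, 0), Cfb)
})
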