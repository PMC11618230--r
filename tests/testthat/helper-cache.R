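# Shared fixtures for the suite. Expensive scenario runs are computed once
# (lazily) and reused across test files; everything is deterministic, so a
# cached result is identical to a fresh one.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

poiseuille_case <- function() fixture("poiseuille", {
  mesh <- generate_tube_mesh(3e-4, 3e-3, 2.5e-5, axial_stretch = 4,
                             wall_grading = 0.8)
  fp <- fluid_properties()
  flow <- solve_steady(mesh, NULL, 0, flow_bc(mean_velocity = 0.015), fp,
                       porosity_params(), flow_config())
  list(mesh = mesh, flow = flow, fp = fp, ubar = 0.015, R = 1.5e-4)
})

tube_run <- function(name) fixture(paste0("run_", name), {
  sc <- build_scenario(name, h_scale = 1.4, end_time = 0.5)
  st <- run_coupled(sc$mesh, sc$ib, sc$params, sc$cfg, wires = sc$wires)
  list(sc = sc, st = st)
})

sidewall_run <- function(name = "sidewall_plasma") fixture(paste0("run_", name), {
  sc <- build_scenario(name, h_scale = 1.3, end_time = 0.25)
  st <- run_coupled(sc$mesh, sc$ib, sc$params, sc$cfg, wires = sc$wires)
  list(sc = sc, st = st)
})

# very coarse tube scenario for checkpoint / CLI tests
tiny_tube_scenario <- function(end_time = 0.08) {
  build_scenario("tube90", h_scale = 2.2, end_time = end_time)
}

# small box with a uniform axial velocity attached, for transport tests
box_transport <- function(nx = 20, ny = 4, nz = 4, ux = 0.01,
                          cfg = transport_config()) {
  m <- generate_box_mesh(2e-3, 4e-4, 4e-4, nx, ny, nz)
  tp <- transport_operators(m, NULL, cfg)
  u <- matrix(0, nrow(m$nodes), 3L)
  u[, 1] <- ux
  tp <- transport_set_flow(tp, u = u, tau_elem = 0)
  list(mesh = m, tp = tp, u = u)
}

# unit icosphere triangulation by octahedron subdivision (for STL tests)
make_sphere_tri <- function(levels = 3) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (l in seq_len(levels)) {
    nf <- nrow(f)
    newf <- matrix(0L, 4L * nf, 3L)
    env <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      id <- env[[k]]
      if (is.null(id)) {
        p <- v[a, ] + v[b, ]
        p <- p / sqrt(sum(p^2))
        v <<- rbind(v, p)
        id <- nrow(v)
        env[[k]] <- id
      }
      id
    }
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[(4 * i - 3):(4 * i), ] <- rbind(c(a, ab, ca), c(ab, b, bc),
                                           c(ca, bc, c3), c(ab, bc, ca))
    }
    f <- newf
  }
  list(vertices = v, triangles = f)
}

arc_s <- function(mesh, p) {
  fdfibrin:::.vessel_coords(p, mesh$geom$curvature_radius)$s
}
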