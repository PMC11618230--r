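test_that("box mesh reproduces exact volume, areas and face closure", {
  m <- generate_box_mesh(1e-3, 5e-4, 5e-4, 4, 2, 2)
  expect_equal(mesh_volume(m), 1e-3 * 5e-4 * 5e-4, tolerance = 1e-12)
  expect_equal(boundary_area(m, "inlet"), 5e-4 * 5e-4, tolerance = 1e-12)
  expect_equal(boundary_area(m, "outlet"), 5e-4 * 5e-4, tolerance = 1e-12)
  expect_lt(mesh_closure_defect(m), 1e-10)
  expect_true(all(m$V > 0))
  # every interior face has two distinct adjacent elements
  interior <- !is.na(m$face_k2)
  expect_true(all(m$face_k1[interior] != m$face_k2[interior]))
  expect_true(all(m$face_ds > 0))
})

test_that("tube mesh matches the analytic cylinder within 2%", {
  m <- generate_tube_mesh(3e-4, 3e-3, 3e-5)
  vol <- pi * 1.5e-4^2 * 3e-3
  expect_lt(abs(mesh_volume(m) - vol) / vol, 0.02)
  disc <- pi * 1.5e-4^2
  expect_lt(abs(boundary_area(m, "inlet") - disc) / disc, 0.02)
  expect_lt(abs(boundary_area(m, "outlet") - disc) / disc, 0.02)
  expect_lt(mesh_closure_defect(m), 1e-10)
  # boundary nodes land exactly on the circle
  wall_nodes <- which(m$node_tag == 3L)
  r <- sqrt(m$nodes[wall_nodes, 2]^2 + m$nodes[wall_nodes, 3]^2)
  expect_equal(max(abs(r - 1.5e-4)), 0, tolerance = 1e-12)
})

test_that("degenerate tube resolution is rejected", {
  expect_error(generate_tube_mesh(3e-4, 3e-3, 3e-4), "target_h")
})

test_that("sidewall mesh approximates the sac volume and tags both ends", {
  m <- generate_sidewall_aneurysm_mesh(4e-3, 8e-3, 4e-2, neck_d = 4e-3,
                                       target_h = 5e-4)
  g <- m$geom
  rv <- g$vessel_d / 2; rs <- g$sac_radius; hc <- g$sac_center[2]
  cap_h <- rv - (hc - rs)
  analytic <- 4 / 3 * pi * rs^3 - pi * cap_h^2 * (3 * rs - cap_h) / 3
  above <- m$centroid[, 2] > rv
  in_sac <- sqrt(rowSums(sweep(m$centroid, 2, g$sac_center)^2)) <= rs
  expect_lt(abs(sum(m$V[in_sac & above]) - analytic) / analytic, 0.10)
  expect_gt(boundary_area(m, "inlet"), 0.5 * pi * rv^2)
  expect_gt(boundary_area(m, "outlet"), 0.5 * pi * rv^2)
  expect_lt(mesh_closure_defect(m), 1e-10)
  expect_false(is.null(g$neck_plane))
})

test_that("straight-vessel variant is produced for infinite curvature", {
  m <- generate_sidewall_aneurysm_mesh(4e-3, 8e-3, Inf, neck_d = 4e-3,
                                       target_h = 6e-4, vessel_length = 1.6e-2)
  cc <- centerline_coords(m, m$nodes[1:10, , drop = FALSE])
  expect_equal(cc$s, m$nodes[1:10, 1])
  expect_equal(cc$tangent[, 1], rep(1, 10))
  expect_lt(mesh_closure_defect(m), 1e-10)
})
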