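test_that("zero refinement levels leave the mesh untouched", {
  m <- generate_box_mesh(5e-4, 2e-4, 2e-4, 3, 2, 2)
  ib <- compute_immersed_boundary(m, NULL)
  expect_identical(refine_near_wires(m, ib, 0), m)
})

test_that("bisection refinement conserves volume and halves local size", {
  m <- generate_box_mesh(6e-4, 3e-4, 3e-4, 4, 2, 2)
  ws <- build_braided_device(0, 3e-5, 90, 1.4e-4, type = "screen",
                             center_s = 3e-4, cell_side = 1.2e-4)
  # screens are built in the y-z plane around the origin of that plane;
  # shift to the box centre
  ws$wires <- lapply(ws$wires, function(w) sweep(w, 2, c(0, -1.5e-4, -1.5e-4)))
  ws$spheres <- fdfibrin:::.sample_spheres(ws$wires, ws$wire_radius)
  ib <- compute_immersed_boundary(m, ws)
  expect_gt(nrow(ib$cut_edges), 0L)
  pre_h <- min(m$h[ib$r_field < 2 * ws$wire_radius])

  r <- refine_near_wires(m, ib, 1, wires = ws)
  # conforming, valid, volume-preserving
  expect_lt(abs(mesh_volume(r) - mesh_volume(m)) / mesh_volume(m), 1e-12)
  expect_lt(mesh_closure_defect(r), 1e-10)
  expect_gt(nrow(r$tets), nrow(m$tets))
  ib2 <- compute_immersed_boundary(r, ws)
  post_h <- min(r$h[ib2$r_field < 2 * ws$wire_radius])
  expect_lte(post_h, pre_h / 2 + 1e-15)
})
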