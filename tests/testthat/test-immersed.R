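test_that("distance field matches a brute-force evaluation", {
  m <- generate_box_mesh(1e-3, 4e-4, 4e-4, 8, 4, 4)
  ws <- build_braided_device(0, 4e-5, 90, 1.8e-4, type = "screen",
                             center_s = 5e-4, cell_side = 1.5e-4)
  ib <- compute_immersed_boundary(m, ws)
  d_exact <- dist_to_wires(m$centroid, ws, cutoff = Inf)
  r_exact <- pmax(d_exact - ws$wire_radius, 0)
  cap <- ib$cutoff - ws$wire_radius
  expect_lt(max(abs(pmin(r_exact, cap) - pmin(ib$r_field, cap))), 1e-12)
})

test_that("element centroid on the centerline has zero wire distance", {
  m <- generate_box_mesh(1e-3, 4e-4, 4e-4, 8, 4, 4)
  cc <- m$centroid[10, ]
  ws <- list(wires = list(rbind(cc + c(-1e-4, 0, 0), cc + c(1e-4, 0, 0))),
             wire_radius = 1e-5,
             spheres = list(centers = rbind(cc), radius = 1e-5))
  class(ws) <- "wire_set"
  ib <- compute_immersed_boundary(m, ws)
  expect_equal(ib$r_field[10], 0)
})

test_that("empty wire set yields no cut edges and an infinite field", {
  m <- generate_box_mesh(5e-4, 2e-4, 2e-4, 3, 2, 2)
  ib <- compute_immersed_boundary(m, NULL)
  expect_equal(nrow(ib$cut_edges), 0L)
  expect_length(ib$ib_nodes, 0L)
  expect_true(all(is.infinite(ib$r_field)))
})

test_that("a screen in a tube cuts edges and tags no-slip nodes", {
  m <- generate_tube_mesh(3e-4, 3e-3, 3e-5)
  ws <- build_braided_device(0, 2e-5, 90, 1.5e-4, type = "screen",
                             center_s = 1.5e-3, cell_side = 1e-4)
  ib <- compute_immersed_boundary(m, ws)
  expect_gt(nrow(ib$cut_edges), 0L)
  expect_gt(length(ib$ib_nodes), 0L)
  # every node strictly inside a wire is a no-slip node
  inside <- which(ib$node_dist < 0)
  expect_true(all(inside %in% ib$ib_nodes))
  # cut edges straddle the wire surface
  d1 <- ib$node_dist[ib$cut_edges[, 1]]
  d2 <- ib$node_dist[ib$cut_edges[, 2]]
  expect_true(all((d1 < 0) != (d2 < 0)))
})
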