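test_that("helical wires lie on the deployment cylinder at the right pitch", {
  ws <- build_braided_device(48, 3.2e-5, 90, 2.375e-3, length = 0.02)
  expect_equal(ws$n_wires, 48L)
  expect_length(ws$wires, 48L)
  for (w in ws$wires[c(1, 25, 48)]) {
    r <- sqrt(w[, 2]^2 + w[, 3]^2)
    expect_lt(max(abs(r - 2.375e-3)), 1e-12)
  }
  # braid angle 90deg -> each wire runs 45deg from the axis on the unrolled
  # cylinder: equal axial and circumferential advance per segment
  w <- ws$wires[[1]]
  dx <- diff(w[, 1])
  dpsi <- diff(atan2(w[, 3], w[, 2]))
  dpsi <- (dpsi + pi) %% (2 * pi) - pi          # unwrap branch jumps
  dcirc <- 2.375e-3 * dpsi
  expect_equal(abs(dcirc / dx), rep(1, length(dx)), tolerance = 1e-9)
})

test_that("sphere sampling overlaps (spacing below the sphere radius)", {
  ws <- build_braided_device(4, 4e-5, 90, 1e-3, length = 5e-3)
  ctr <- ws$spheres$centers
  gaps <- sqrt(rowSums(diff(ctr)^2))
  # within one wire consecutive spheres are closer than the radius
  expect_lt(stats::median(gaps), ws$sphere_radius)
})

test_that("metal coverage grows with braid angle at fixed wire count", {
  cov <- vapply(c(60, 90, 120, 150), function(b)
    device_coverage_fraction(
      build_braided_device(48, 3e-5, b, 2e-3, length = 0.016)), 1)
  expect_true(all(diff(cov) > 0))
})

test_that("screens place both wire families in the disc at the cell angle", {
  ws <- build_braided_device(0, 2e-5, 150, 1.5e-4, type = "screen",
                             center_s = 1.5e-3, cell_side = 1e-4)
  expect_equal(ws$type, "screen")
  pts <- do.call(rbind, ws$wires)
  expect_true(all(abs(pts[, 1] - 1.5e-3) < 1e-12))        # planar
  expect_true(all(pts[, 2]^2 + pts[, 3]^2 <= (1.5e-4)^2 + 1e-12))
  dirs <- t(vapply(ws$wires, function(w) {
    d <- w[nrow(w), 2:3] - w[1, 2:3]; d / sqrt(sum(d^2))
  }, numeric(2)))
  ang <- sort(unique(round(atan2(dirs[, 2], dirs[, 1]) / pi * 180, 6)))
  ang <- unique(round(ang %% 180, 6))
  expect_length(ang, 2L)
  # the rhombic cell has internal angles {gamma, 180 - gamma}; the crossing
  # angle between the line families measures the supplementary pair
  crossing <- min(abs(diff(ang)), 180 - abs(diff(ang)))
  expect_equal(crossing, 30, tolerance = 1e-6)
})

test_that("orifice trimming keeps only wire points near the sac", {
  ws <- build_braided_device(8, 3e-5, 90, 1.985e-3, length = 0.016,
                             curvature_radius = 4e-2)
  ctr <- c(0, 5.2e-3, 0)
  tw <- trim_wires_to_orifice(ws, ctr, 4e-3)
  pts <- do.call(rbind, tw$wires)
  d <- sqrt(colSums((t(pts) - ctr)^2))
  expect_true(all(d <= 4e-3 + 1e-12))
  expect_gt(nrow(pts), 0)
})
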