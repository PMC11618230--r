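test_that("tube scenarios carry physiologic inlet concentrations", {
  sc <- tiny_tube_scenario()
  expect_equal(unname(sc$params$inlet),
               c(1.4, 2.41, 0, 7.0, 0, 0))
  expect_equal(sc$params$bc$mean_velocity, 0.015)
  expect_equal(sc$config$geometry$diameter, 3e-4)
  expect_equal(sc$wires$type, "screen")
  expect_equal(sc$wires$wire_radius, 1e-5)
})

test_that("the fibrinogen-only scenario disables the thrombin pathway", {
  cfgf <- system.file("extdata", "scenarios", "sidewall_fibrinogen_only.yaml",
                      package = "fdfibrin")
  cfg <- read_run_config(cfgf)
  expect_equal(cfg$reaction$Kwt, 0)
  expect_equal(cfg$reaction$Kth, 0)
  expect_equal(cfg$inlet$PT, 0)
  expect_equal(fibrinogen_mg_dl_to_uM(cfg$inlet$Fg_mg_dl), 9.706, tolerance = 1e-3)
  expect_equal(cfg$flow$flow_rate, 4e-6)
})

test_that("the sidewall plasma scenario matches its stated dimensions", {
  cfgf <- system.file("extdata", "scenarios", "sidewall_plasma.yaml",
                      package = "fdfibrin")
  cfg <- read_run_config(cfgf)
  expect_equal(cfg$geometry$vessel_d, 4e-3)
  expect_equal(cfg$geometry$aneurysm_d, 8e-3)
  expect_equal(cfg$geometry$curvature_radius, 4e-2)
  expect_equal(cfg$device$n_wires, 48)
  expect_equal(cfg$device$wire_diameter, 3e-5)
  expect_equal(cfg$flow$flow_rate, 4e-6)
})

test_that("unknown scenario names are rejected", {
  expect_error(build_scenario("no_such_scenario"), "unknown scenario")
})

test_that("the 150-degree screen has denser wires than the 90-degree one", {
  s90 <- build_braided_device(0, 2e-5, 90, 1.5e-4, type = "screen",
                              cell_side = 1e-4)
  s150 <- build_braided_device(0, 2e-5, 150, 1.5e-4, type = "screen",
                               cell_side = 1e-4)
  len <- function(ws) sum(vapply(ws$wires, function(w)
    sum(sqrt(rowSums(diff(w)^2))), 1))
  # equal cell side, smaller pore area per cell -> more wire length in the disc
  expect_gt(len(s150), len(s90))
})
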