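test_that("Hill switch has the expected shape and limits", {
  expect_equal(hill(0, 2), 0)
  for (n in c(1, 2, 4, 8)) expect_equal(hill(1, n), 0.5)
  expect_equal(hill(2, 2), 0.8)
  x <- seq(0, 50, by = 0.25)
  h <- hill(x, 4)
  expect_true(all(diff(h) > 0))            # strictly increasing
  expect_true(all(h >= 0 & h < 1))
  expect_equal(hill(1e9, 4), 1, tolerance = 1e-12)
  expect_error(hill(-1, 2), "x must be")
})

test_that("wire proximity switch is ~1 on the wire and decays with distance", {
  r0 <- 2e-5
  expect_equal(wire_proximity_switch(0, r0, 4), 1)
  expect_equal(wire_proximity_switch(r0, r0, 4), 0.5)
  expect_equal(wire_proximity_switch(10 * r0, r0, 4), 1 / (1 + 1e4),
               tolerance = 1e-12)
  r <- seq(0, 10 * r0, length.out = 50)
  expect_true(all(diff(wire_proximity_switch(r, r0, 4)) <= 0))
  # literal printed orientation increases with distance instead
  expect_equal(wire_proximity_switch(0, r0, 4, literal = TRUE), 0)
  expect_equal(wire_proximity_switch(r0, r0, 4, literal = TRUE), 0.5)
})

test_that("source terms match a hand evaluation with switches off", {
  p <- reaction_params(Kat = 0.5, Kth = 2, Km = 1)
  C <- c(PT = 1.4, AT = 2.41, Th = 0.1, Fg = 7, Fn = 0, Fb = 0)
  S <- source_terms(C, tau = 0, r = 1e4 * p$r0, Cfb_avg = 0, p = p)
  expect_equal(S[["Th"]], -p$Kat * 2.41 * 0.1, tolerance = 1e-10)
  expect_equal(S[["AT"]], -p$Kat * 2.41 * 0.1, tolerance = 1e-10)
  expect_equal(S[["Fg"]], -p$Kth * 0.1 * 7 / (p$Km + 7), tolerance = 1e-10)
  expect_equal(S[["PT"]], 0, tolerance = 1e-12)
  # all-zero state gives zero sources
  expect_equal(unname(source_terms(rep(0, 6), 1, 0, 0, p)), rep(0, 6))
})

test_that("fibrin-family conservation and thrombin bookkeeping hold for random states", {
  set.seed(42)
  for (draw in 1:5) {
    p <- reaction_params(Kwt = runif(1, 0, 5), Kat = runif(1, 0, 2),
                         Kth = runif(1, 0, 5), Km = runif(1, 0.1, 10),
                         Kss = runif(1, 0, 5), Kwa = runif(1, 0, 100),
                         Kb = runif(1, 0, 5), tau0 = runif(1, 0.1, 3),
                         r0 = runif(1, 1e-5, 1e-3), n_hill = sample(1:8, 1))
    n <- 2000L
    C <- matrix(runif(6 * n, 0, 10), n, 6)
    tau <- runif(n, 0, 5); r <- runif(n, 0, 1e-3); cavg <- runif(n, 0, 10)
    S <- source_terms(C, tau, r, cavg, p)
    scale <- pmax(abs(S[, 4]), abs(S[, 5]), abs(S[, 6]), 1e-300)
    expect_lt(max(abs(S[, 4] + S[, 5] + S[, 6]) / scale), 1e-12)
    scale2 <- pmax(abs(S[, 1]), abs(S[, 2]), abs(S[, 3]), 1e-300)
    expect_lt(max(abs(S[, 1] + S[, 3] - S[, 2]) / scale2), 1e-12)
  }
})

test_that("0D batch kinetics match closed forms when inhibition is off", {
  p <- reaction_params(Kwt = 2, Kat = 0, Kth = 0, Kss = 0, Kwa = 0, Kb = 0)
  out <- integrate_batch(c(1.4, 2.41, 0, 7, 0, 0), tau = 0, r = 0, p = p,
                         t_end = 2, dt = 1e-3)
  tt <- out$time
  expect_equal(out$C[, "PT"], 1.4 * exp(-2 * tt), tolerance = 1e-6)
  expect_equal(out$C[, "Th"], 1.4 * (1 - exp(-2 * tt)), tolerance = 1e-6)
  expect_equal(out$C[, "Fg"], rep(7, length(tt)))
})

test_that("0D kinetics match an independent stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- reaction_params()
  C0 <- c(1.4, 2.41, 0, 7, 0, 0)
  tau <- 1; r <- 1e-5
  out <- integrate_batch(C0, tau, r, p, t_end = 2, dt = 2e-4)
  f_ode <- function(t, y, parms) {
    list(as.numeric(source_terms(pmax(y, 0), tau, r, Cfb_avg = y[6], p = p)))
  }
  ref <- deSolve::lsoda(C0, times = out$time, func = f_ode, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  rel <- max(abs(out$C - ref[, -1])) / max(abs(ref[, -1]))
  expect_lt(rel, 1e-4)
  # fibrin family total conserved along the trajectory
  fib_tot <- rowSums(out$C[, 4:6])
  expect_lt(max(abs(fib_tot - fib_tot[1])) / fib_tot[1], 1e-8)
})

test_that("state with no flow, no thrombin and no wires stays constant", {
  p <- reaction_params()
  out <- integrate_batch(c(1.4, 2.41, 0, 7, 0, 0), tau = 0, r = 1e4 * p$r0,
                         p = p, t_end = 1, dt = 1e-3)
  expect_equal(out$C[nrow(out$C), ], out$C[1, ], tolerance = 1e-9)
})

test_that("explicit integration never leaves concentrations negative", {
  p <- reaction_params(Kat = 5, Kwa = 100)
  out <- integrate_batch(c(0.1, 5, 2, 1, 3, 1), tau = 3, r = 0, p = p,
                         t_end = 1, dt = 1e-3)
  expect_true(all(out$C >= 0))
})
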