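#' Hill switching function
#'
#' Smooth sigmoidal step `x^n / (1 + x^n)` used to threshold shear stress,
#' wire proximity and clot density. Strictly increasing, 0 at x = 0,
#' 0.5 at x = 1, and tends to 1 as x grows.
#'
#' @param x non-negative dimensionless ratio (vectorized)
#' @param n Hill exponent (>= 1)
#' @return values in [0, 1)
#' @export
hill <- function(x, n) {
  if (any(x < 0)) stop("hill: x must be >= 0")
  if (n < 1) stop("hill: n must be >= 1")
  xn <- x^n
  out <- xn / (1 + xn)
  out[is.infinite(xn)] <- 1   # overflow guard for very large x
  out
}

#' Wire-proximity switch
#'
#' Switch that is ~1 on a wire surface and decays to 0 far from it:
#' `1 - hill(r/r0, n)`, evaluating to 1 at r = 0 and 0.5 at r = r0. The
#' literal increasing form `hill(r/r0, n)` can be selected via
#' `reaction_params(wire_switch_literal = TRUE)` where exact reproduction of
#' the printed source terms is wanted.
#'
#' @param r distance to the nearest wire surface (m), vectorized
#' @param r0 distance threshold (m)
#' @param n Hill exponent
#' @param literal use the increasing form instead of the proximity form
#' @return values in [0, 1]
#' @export
wire_proximity_switch <- function(r, r0, n, literal = FALSE) {
  h <- hill(r / r0, n)
  if (literal) h else 1 - h
}

#' Reaction source terms for the six species
#'
#' Evaluates, per sample (element), the reduced coagulation source vector
#' (S_PT, S_AT, S_Th, S_Fg, S_Fn, S_Fb) in uM/s:
#' \itemize{
#'  \item S_PT = -Kwt w(r) C_PT (thrombin production consumes prothrombin
#'        near wires)
#'  \item S_AT = -Kat C_AT C_Th (antithrombin consumed inhibiting thrombin)
#'  \item S_Th = Kwt w(r) C_PT - Kat C_AT C_Th
#'  \item S_Fg = -Kth C_Th C_Fg/(Km + C_Fg) - Kss phi(tau/tau0) C_Fg
#'  \item S_Fn = -S_Fg - Kwa w(r) C_Fn - Kb Cfb_avg C_Fn
#'  \item S_Fb = Kwa w(r) C_Fn + Kb Cfb_avg C_Fn
#' }
#' where w(r) is [wire_proximity_switch] and phi the [hill] switch. The
#' fibrin-family terms cancel pairwise, so S_Fg + S_Fn + S_Fb = 0 exactly,
#' and S_PT + S_Th = S_AT.
#'
#' The fibrin-fibrin adhesion term uses the neighbourhood-averaged bounded
#' fibrin `Cfb_avg` (fibre-length average), not the local C_Fb, so that
#' bounded fibrin can seed growth in adjacent cells.
#'
#' @param C matrix (n x 6) or 6-vector of concentrations (uM), columns in
#'   [SPECIES] order
#' @param tau shear-stress magnitude (Pa), scalar or length-n
#' @param r distance to nearest wire surface (m), scalar or length-n
#' @param Cfb_avg neighbour-averaged bounded fibrin (uM), scalar or length-n
#' @param p [reaction_params]
#' @param switches optional list(w, sw_tau) of precomputed switch values
#'   (the wire switch is constant per run and the shear switch per flow
#'   solve, so hot loops precompute them once)
#' @return matrix (n x 6) or 6-vector of rates (uM/s), matching the input shape
#' @export
source_terms <- function(C, tau, r, Cfb_avg, p, switches = NULL) {
  vec_in <- is.null(dim(C))
  if (vec_in) C <- matrix(C, nrow = 1L)
  stopifnot(ncol(C) == 6L)
  if (is.null(switches)) {
    w <- wire_proximity_switch(r, p$r0, p$n_hill,
                               literal = p$wire_switch_literal)
    sw_tau <- hill(tau / p$tau0, p$n_hill)
  } else {
    w <- switches$w; sw_tau <- switches$sw_tau
  }

  Cpt <- C[, 1L]; Cat <- C[, 2L]; Cth <- C[, 3L]
  Cfg <- C[, 4L]; Cfn <- C[, 5L]

  prod_th  <- p$Kwt * w * Cpt              # wire-stimulated thrombin production
  inhib    <- p$Kat * Cat * Cth            # antithrombin inhibition
  fib_th   <- p$Kth * Cth * Cfg / (p$Km + Cfg)  # thrombin pathway
  fib_ss   <- p$Kss * sw_tau * Cfg         # shear pathway
  adh_wire <- p$Kwa * w * Cfn              # adhesion to wires
  adh_fib  <- p$Kb * Cfb_avg * Cfn         # adhesion to bounded fibrin

  S <- cbind(-prod_th,
             -inhib,
             prod_th - inhib,
             -(fib_th + fib_ss),
             fib_th + fib_ss - adh_wire - adh_fib,
             adh_wire + adh_fib)
  colnames(S) <- SPECIES
  if (vec_in) S[1L, ] else S
}

#' Well-mixed (0D) batch integration of the reaction network
#'
#' Integrates dC/dt = S(C) at fixed shear and wire distance with an explicit
#' 4th-order Runge-Kutta scheme, clipping any negative concentration to zero
#' after each step (explicit integration of stiff sinks can undershoot; the
#' cumulative clipped mass is reported). Used as a transport-free oracle for
#' the source terms.
#'
#' @param C0 initial 6-vector of concentrations (uM)
#' @param tau constant shear magnitude (Pa)
#' @param r constant wire distance (m)
#' @param p [reaction_params]
#' @param t_end end time (s)
#' @param dt timestep (s); must resolve the fastest reaction
#' @return list with `time` (vector), `C` (ntime x 6 matrix of trajectories)
#'   and `clipped` (total clipped mass, uM)
#' @export
integrate_batch <- function(C0, tau, r, p, t_end, dt) {
  if (dt <= 0) stop("integrate_batch: dt must be > 0")
  nt <- max(1L, ceiling(t_end / dt))
  dt <- t_end / nt
  C <- matrix(NA_real_, nt + 1L, 6L, dimnames = list(NULL, SPECIES))
  C[1L, ] <- C0
  clipped <- 0
  f <- function(x) source_terms(x, tau, r, Cfb_avg = x[6L], p = p)
  x <- as.numeric(C0)
  for (i in seq_len(nt)) {
    k1 <- f(x)
    k2 <- f(pmax(x + dt / 2 * k1, 0))
    k3 <- f(pmax(x + dt / 2 * k2, 0))
    k4 <- f(pmax(x + dt * k3, 0))
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    neg <- x < 0
    if (any(neg)) {
      clipped <- clipped + sum(-x[neg])
      x[neg] <- 0
    }
    C[i + 1L, ] <- x
  }
  list(time = seq(0, t_end, length.out = nt + 1L), C = C, clipped = clipped)
}
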