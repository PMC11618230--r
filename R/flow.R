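# Fractional-step (projection) solver for steady incompressible flow with a
# Darcy clot force, discretized with linear (P1) finite elements on tets.
# Advection is explicit; viscous and porous terms are implicit in the
# velocity prediction; a pressure-Poisson solve projects the predicted
# velocity onto a (weakly) divergence-free field.

#' Precompute finite-element operators for a mesh
#'
#' Builds the sparse operators used by the flow solver and shear evaluation:
#' per-element P1 gradient matrices Gx/Gy/Gz (element x node), the volume
#' scatter matrix S (node x element, entries V/4), the element-to-node
#' averaging matrix, the lumped mass vector, and the pressure Laplacian.
#'
#' @param mesh a `tet_mesh`
#' @return list of operators (cached by [solve_steady])
#' @export
flow_operators <- function(mesh) {
  nodes <- mesh$nodes; tets <- mesh$tets
  ne <- nrow(tets); nn <- nrow(nodes)
  p1 <- nodes[tets[, 1], , drop = FALSE]; p2 <- nodes[tets[, 2], , drop = FALSE]
  p3 <- nodes[tets[, 3], , drop = FALSE]; p4 <- nodes[tets[, 4], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1; c3 <- p4 - p1
  det <- .det3(a, b, c3)              # = 6V > 0
  # rows of inv([a b c]^T known as A columns): gradients of barycentric coords
  # A = [a | b | c] (columns); inv(A) rows via cross products / det
  g2 <- .cross3(b, c3) / det          # grad N2
  g3 <- .cross3(c3, a) / det          # grad N3
  g4 <- .cross3(a, b) / det           # grad N4
  g1 <- -(g2 + g3 + g4)
  G <- list(g1, g2, g3, g4)

  ii <- rep(seq_len(ne), 4L)
  jj <- as.vector(tets)
  Gx <- Matrix::sparseMatrix(i = ii, j = jj,
          x = c(g1[, 1], g2[, 1], g3[, 1], g4[, 1]), dims = c(ne, nn))
  Gy <- Matrix::sparseMatrix(i = ii, j = jj,
          x = c(g1[, 2], g2[, 2], g3[, 2], g4[, 2]), dims = c(ne, nn))
  Gz <- Matrix::sparseMatrix(i = ii, j = jj,
          x = c(g1[, 3], g2[, 3], g3[, 3], g4[, 3]), dims = c(ne, nn))
  S <- Matrix::sparseMatrix(i = jj, j = ii, x = rep(mesh$V / 4, 4L),
                            dims = c(nn, ne))
  E2N <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(0.25, 4L * ne),
                              dims = c(ne, nn))
  ML <- as.numeric(S %*% rep(1, ne))

  # triplet skeleton for stiffness assembly with per-element coefficients
  si <- integer(16L * ne); sj <- integer(16L * ne)
  gg <- matrix(0, ne, 16L)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1L
    idx <- (k - 1L) * ne + seq_len(ne)
    si[idx] <- tets[, i]; sj[idx] <- tets[, j]
    gg[, k] <- rowSums(G[[i]] * G[[j]])
  }
  ops <- list(ne = ne, nn = nn, Gx = Gx, Gy = Gy, Gz = Gz, S = S, E2N = E2N,
              ML = ML, stiff_i = si, stiff_j = sj, stiff_gg = gg, V = mesh$V)
  ops$L1 <- .assemble_stiffness(ops, rep(1, ne))   # unit-coefficient Laplacian
  ops
}

.assemble_stiffness <- function(ops, coef_elem) {
  x <- as.vector(ops$stiff_gg * (coef_elem * ops$V))
  Matrix::sparseMatrix(i = ops$stiff_i, j = ops$stiff_j, x = x,
                       dims = c(ops$nn, ops$nn))
}

#' Darcy (porosity) force density of the accumulated clot
#'
#' F = -pi_coeff * phi(C_Fb / Cfb0) * u, the momentum sink through the
#' porous fibrin. Antiparallel to the velocity; saturates at -pi_coeff * u.
#'
#' @param Cfb bounded-fibrin concentration (uM), per element or scalar
#' @param u velocity, matrix (n x 3) or 3-vector
#' @param pp [porosity_params]
#' @return force density, same shape as `u` (N/m^3)
#' @export
darcy_force <- function(Cfb, u, pp) {
  if (any(Cfb < 0)) stop("darcy_force: Cfb must be >= 0")
  phi <- hill(Cfb / pp$Cfb0, pp$n_hill)
  if (is.null(dim(u))) -pp$pi_coeff * phi * u else -pp$pi_coeff * phi * u
}

#' Flow solver configuration
#'
#' @param eps1 convergence tolerance on the per-step velocity change
#'   max|u_new - u_old| (m/s)
#' @param max_iters maximum pseudo-timesteps
#' @param cou advective Courant factor (< 1)
#' @param art_visc artificial-viscosity coefficient c in
#'   mu_art = 0.5 c rho |u| h (stabilizes coarse high-Peclet meshes; the
#'   Poiseuille profile and the shear evaluation are unaffected because the
#'   profile at prescribed flow is viscosity-independent and tau uses the
#'   physical mu)
#' @param verbose print residuals every 100 steps
#' @return list of class `flow_config`
#' @export
flow_config <- function(eps1 = 1e-4, max_iters = 4000, cou = 0.8,
                        art_visc = 1, verbose = FALSE) {
  stopifnot(eps1 > 0, cou > 0, cou < 1)
  structure(list(eps1 = eps1, max_iters = max_iters, cou = cou,
                 art_visc = art_visc, verbose = verbose),
            class = "flow_config")
}

#' Inflow boundary condition specification
#'
#' @param type "velocity" (parabolic profile at prescribed mean velocity or
#'   flow rate) or "pressure" (fixed pressure drop, velocity free at inlet)
#' @param mean_velocity mean inlet velocity (m/s), for type "velocity"
#' @param flow_rate volumetric flow rate (m^3/s); overrides mean_velocity and
#'   rescales the discrete profile so the inlet flux matches exactly
#' @param dp driving pressure difference inlet minus outlet (Pa), for type
#'   "pressure"
#' @return list of class `flow_bc`
#' @export
flow_bc <- function(type = c("velocity", "pressure"), mean_velocity = NULL,
                    flow_rate = NULL, dp = NULL) {
  type <- match.arg(type)
  if (type == "velocity" && is.null(mean_velocity) && is.null(flow_rate))
    stop("velocity BC needs mean_velocity or flow_rate")
  if (type == "pressure" && is.null(dp)) stop("pressure BC needs dp")
  structure(list(type = type, mean_velocity = mean_velocity,
                 flow_rate = flow_rate, dp = dp), class = "flow_bc")
}

# nodal parabolic inlet profile (3 columns), zero elsewhere
.inlet_profile <- function(mesh, bc) {
  nn <- nrow(mesh$nodes)
  u <- matrix(0, nn, 3L)
  inlet_nodes <- which(mesh$node_tag == 1L)
  if (!length(inlet_nodes)) stop("mesh has no inlet nodes")
  cc <- centerline_coords(mesh, mesh$nodes[inlet_nodes, , drop = FALSE])
  R <- .vessel_radius(mesh)
  ubar <- if (!is.null(bc$flow_rate)) bc$flow_rate / (pi * R^2) else bc$mean_velocity
  mag <- 2 * ubar * pmax(1 - (cc$d / R)^2, 0)
  u[inlet_nodes, ] <- cc$tangent * mag
  if (!is.null(bc$flow_rate)) {
    q0 <- -boundary_flux(mesh, u, "inlet")   # inflow positive
    if (q0 <= 0) stop("inlet profile produced no inflow")
    u[inlet_nodes, ] <- u[inlet_nodes, ] * (bc$flow_rate / q0)
  }
  u
}

.vessel_radius <- function(mesh) {
  g <- mesh$geom
  if (identical(g$type, "tube")) g$radius
  else if (identical(g$type, "sidewall")) g$vessel_d / 2
  else stop("no vessel radius defined for geometry type '", g$type, "'")
}

#' Volumetric flux through a tagged boundary (outward positive)
#'
#' @param mesh a `tet_mesh`
#' @param u nodal velocity (n_nodes x 3)
#' @param tag "inlet", "outlet" or "wall"
#' @export
boundary_flux <- function(mesh, u, tag = c("inlet", "outlet", "wall")) {
  tag <- match.arg(tag)
  code <- match(tag, c("inlet", "outlet", "wall"))
  f <- which(mesh$face_tag == code)
  if (!length(f)) return(0)
  uf <- (u[mesh$face_nodes[f, 1], , drop = FALSE] +
         u[mesh$face_nodes[f, 2], , drop = FALSE] +
         u[mesh$face_nodes[f, 3], , drop = FALSE]) / 3
  sum(rowSums(uf * mesh$face_normal[f, , drop = FALSE]) * mesh$face_area[f])
}

#' Solve steady incompressible flow with the Darcy clot force
#'
#' Fractional-step pseudo-time iteration: implicit viscous+porous velocity
#' prediction, pressure-Poisson solve, velocity correction, repeated until
#' the normalized per-step velocity change max|u_new - u_old| / u_ref drops
#' below `cfg$eps1`. No-slip is imposed on walls and on all immersed-boundary
#' nodes; the outlet is traction-free with fixed pressure.
#'
#' @param mesh a `tet_mesh`
#' @param ib an `immersed_boundary` (or NULL for no device)
#' @param Cfb per-element bounded fibrin (uM), scalar 0 for unclotted
#' @param bc a [flow_bc]
#' @param fp [fluid_properties]
#' @param pp [porosity_params]
#' @param cfg [flow_config]
#' @param ops optional cached [flow_operators]
#' @param init optional list(u, p) warm start
#' @return object of class `flow_state`: `u` (nodal, m/s), `p` (nodal, Pa),
#'   `tau_elem` (Pa), `residual_history`, `converged`, `dt`, `u_ref`
#' @export
solve_steady <- function(mesh, ib = NULL, Cfb = 0, bc, fp, pp, cfg = flow_config(),
                         ops = NULL, init = NULL) {
  if (is.null(ops)) ops <- flow_operators(mesh)
  ne <- ops$ne; nn <- ops$nn
  if (length(Cfb) == 1L) Cfb <- rep(Cfb, ne)
  phi <- hill(Cfb / pp$Cfb0, pp$n_hill)
  pc <- pp$pi_coeff * phi                     # porous coefficient per element

  dir_nodes <- which(mesh$node_tag == 3L)     # walls
  if (!is.null(ib) && length(ib$ib_nodes))
    dir_nodes <- union(dir_nodes, ib$ib_nodes)
  u_dir <- matrix(0, nn, 3L)
  if (bc$type == "velocity") {
    u_dir <- .inlet_profile(mesh, bc)
    u_dir[dir_nodes, ] <- 0                   # wall priority incl. rim
    dir_nodes <- union(dir_nodes, which(mesh$node_tag == 1L))
  }
  dir_nodes <- sort(dir_nodes)
  free <- setdiff(seq_len(nn), dir_nodes)

  # pressure Dirichlet set: outlet always; inlet too under a pressure BC
  p_fix <- which(mesh$node_tag == 2L)
  p0 <- numeric(nn)
  if (bc$type == "pressure") {
    inlet_n <- which(mesh$node_tag == 1L)
    p_fix <- union(p_fix, inlet_n)
    p0[inlet_n] <- bc$dp
  }
  if (!length(p_fix)) stop("singular pressure system: mesh has no outlet")
  p_free <- setdiff(seq_len(nn), p_fix)
  Lp <- ops$L1
  Lp_ff <- Lp[p_free, p_free, drop = FALSE]
  Lp_chol <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Lp_ff), "CsparseMatrix"),
                              LDL = FALSE)

  u <- if (!is.null(init$u)) init$u else matrix(0, nn, 3L)
  u[dir_nodes, ] <- u_dir[dir_nodes, ]
  p <- if (!is.null(init$p)) init$p else p0

  u_ref <- if (bc$type == "velocity") max(sqrt(rowSums(u_dir^2))) else NA_real_
  rho <- fp$rho; mu <- fp$mu
  hmin_e <- mesh$h

  resid_hist <- numeric(0)
  converged <- FALSE
  it <- 0L
  A_chol <- NULL; Afc <- NULL; dt <- NA_real_; u_cap <- NA_real_

  refactor <- function(speed_scale) {
    ue <- cbind(ops$E2N %*% u[, 1], ops$E2N %*% u[, 2], ops$E2N %*% u[, 3])
    spd_e <- sqrt(rowSums(as.matrix(ue)^2))
    mu_art <- 0.5 * cfg$art_visc * rho * spd_e * hmin_e
    dt <<- cfg$cou * min(hmin_e / pmax(spd_e, 0.3 * speed_scale))
    A <- .assemble_stiffness(ops, mu + mu_art) +
      Matrix::Diagonal(nn, rho / dt * ops$ML + as.numeric(ops$S %*% pc))
    A_chol <<- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(
      A[free, free, drop = FALSE]), "CsparseMatrix"), LDL = FALSE)
    Afc <<- A[free, dir_nodes, drop = FALSE]
    u_cap <<- 1.5 * max(max(spd_e), speed_scale)
  }

  speed_scale0 <- if (bc$type == "velocity") u_ref else {
    # rough Poiseuille estimate from the driving pressure
    R <- tryCatch(.vessel_radius(mesh), error = function(e) max(mesh$h) * 5)
    Lx <- diff(range(mesh$nodes[, 1]))
    bc$dp * R^2 / (8 * mu * Lx) / max(1, mean(pc) * R^2 / mu + 1)
  }
  # floor guards the quiescent case (zero prescribed inflow)
  speed_scale <- max(speed_scale0, 1e-9)
  refactor(speed_scale)

  while (it < cfg$max_iters) {
    it <- it + 1L
    # explicit advection at elements, scattered to nodes
    ue <- cbind(as.numeric(ops$E2N %*% u[, 1]), as.numeric(ops$E2N %*% u[, 2]),
                as.numeric(ops$E2N %*% u[, 3]))
    spd_max <- sqrt(max(rowSums(ue^2)))
    if (spd_max > u_cap) refactor(max(spd_max, speed_scale))

    u_old <- u
    ustar <- matrix(0, nn, 3L)
    for (cmp in 1:3) {
      gcx <- as.numeric(ops$Gx %*% u[, cmp])
      gcy <- as.numeric(ops$Gy %*% u[, cmp])
      gcz <- as.numeric(ops$Gz %*% u[, cmp])
      adv_e <- ue[, 1] * gcx + ue[, 2] * gcy + ue[, 3] * gcz
      gpe <- switch(cmp, as.numeric(ops$Gx %*% p), as.numeric(ops$Gy %*% p),
                    as.numeric(ops$Gz %*% p))
      rhs <- rho / dt * ops$ML * u[, cmp] -
        as.numeric(ops$S %*% (rho * adv_e + gpe))
      b <- rhs[free] - as.numeric(Afc %*% u_dir[dir_nodes, cmp])
      sol <- as.numeric(Matrix::solve(A_chol, b, system = "A"))
      ustar[free, cmp] <- sol
      ustar[dir_nodes, cmp] <- u_dir[dir_nodes, cmp]
    }

    div_e <- as.numeric(ops$Gx %*% ustar[, 1]) +
             as.numeric(ops$Gy %*% ustar[, 2]) +
             as.numeric(ops$Gz %*% ustar[, 3])
    bp <- -rho / dt * as.numeric(ops$S %*% div_e)
    dp <- numeric(nn)
    dp[p_free] <- as.numeric(Matrix::solve(Lp_chol, bp[p_free], system = "A"))

    for (cmp in 1:3) {
      gdp <- switch(cmp, as.numeric(ops$Gx %*% dp), as.numeric(ops$Gy %*% dp),
                    as.numeric(ops$Gz %*% dp))
      u[, cmp] <- ustar[, cmp] - dt / rho * as.numeric(ops$S %*% gdp) / ops$ML
    }
    u[dir_nodes, ] <- u_dir[dir_nodes, ]
    p <- p + dp

    if (is.na(u_ref)) u_ref <- max(sqrt(max(rowSums(u^2))), 1e-12)
    # convergence measure: the per-step velocity change du = u_new - u_old
    # (a velocity, m/s) -- the same scale used by the coupling trigger
    resid <- max(abs(u - u_old))
    resid_hist[it] <- resid
    if (cfg$verbose && it %% 100L == 0L)
      message(sprintf("  flow iter %d  resid %.3e", it, resid))
    if (!is.finite(resid)) stop("flow solver diverged (non-finite residual)")
    if (resid < cfg$eps1) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("flow solver: not converged after %d iters (resid %.3e)",
                    it, resid_hist[it]))

  st <- list(u = u, p = p, tau_elem = shear_stress_from_ops(u, ops, fp),
             residual_history = resid_hist, converged = converged,
             iterations = it, dt = dt, u_ref = u_ref,
             dir_nodes = dir_nodes, Cfb_at_solve = Cfb)
  class(st) <- "flow_state"
  st
}

#' @export
print.flow_state <- function(x, ...) {
  cat("flow_state:", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(last resid %.2e)\n", utils::tail(x$residual_history, 1)))
  cat("  max speed", format(max(sqrt(rowSums(x$u^2))), digits = 4), "m/s;",
      "max tau", format(max(x$tau_elem), digits = 4), "Pa\n")
  invisible(x)
}

#' Per-element shear-stress magnitude
#'
#' tau = mu * gamma_dot with gamma_dot = sqrt(2 e_ij e_ij), the second
#' invariant of the strain-rate tensor, evaluated from the element-constant
#' P1 velocity gradient.
#'
#' @param flow a `flow_state` or a nodal velocity matrix
#' @param mesh a `tet_mesh`
#' @param fp [fluid_properties]
#' @param ops optional cached operators
#' @return per-element tau (Pa)
#' @export
shear_stress <- function(flow, mesh, fp, ops = NULL) {
  u <- if (inherits(flow, "flow_state")) flow$u else flow
  if (is.null(ops)) ops <- flow_operators(mesh)
  shear_stress_from_ops(u, ops, fp)
}

shear_stress_from_ops <- function(u, ops, fp) {
  dux <- as.numeric(ops$Gx %*% u[, 1]); duy <- as.numeric(ops$Gy %*% u[, 1])
  duz <- as.numeric(ops$Gz %*% u[, 1])
  dvx <- as.numeric(ops$Gx %*% u[, 2]); dvy <- as.numeric(ops$Gy %*% u[, 2])
  dvz <- as.numeric(ops$Gz %*% u[, 2])
  dwx <- as.numeric(ops$Gx %*% u[, 3]); dwy <- as.numeric(ops$Gy %*% u[, 3])
  dwz <- as.numeric(ops$Gz %*% u[, 3])
  e11 <- dux; e22 <- dvy; e33 <- dwz
  e12 <- 0.5 * (duy + dvx); e13 <- 0.5 * (duz + dwx); e23 <- 0.5 * (dvz + dwy)
  ee <- e11^2 + e22^2 + e33^2 + 2 * (e12^2 + e13^2 + e23^2)
  fp$mu * sqrt(2 * ee)
}

#' Wall shear estimate for a circular tube
#'
#' Estimates the wall shear stress from the per-element tau field of a tube
#' flow: area-weighted mean over lateral-wall faces of the adjacent element's
#' tau, extrapolated to the wall radius via the element's radial chord
#' midpoint (the radius at which an element-constant P1 gradient samples a
#' linear shear profile). Elements whose four nodes all lie on the wall
#' (boundary slivers with identically zero velocity) carry no flow
#' information and are excluded.
#'
#' @param mesh a tube `tet_mesh`
#' @param flow a `flow_state`
#' @param x_range optional axial window (m) to avoid end effects
#' @return estimated wall shear (Pa)
#' @export
tube_wall_shear <- function(mesh, flow, x_range = NULL) {
  R <- .vessel_radius(mesh)
  wf <- which(mesh$face_tag == 3L)
  we <- mesh$face_k1[wf]
  if (!is.null(x_range)) {
    keep <- mesh$centroid[we, 1] > x_range[1] & mesh$centroid[we, 1] < x_range[2]
    wf <- wf[keep]; we <- we[keep]
  }
  nwall <- rowSums(matrix(mesh$node_tag[mesh$tets[we, ]] == 3L, ncol = 4))
  keep <- nwall < 4L
  wf <- wf[keep]; we <- we[keep]
  rn <- sqrt(mesh$nodes[, 2]^2 + mesh$nodes[, 3]^2)
  rmat <- matrix(rn[mesh$tets[we, ]], ncol = 4)
  rmid <- (apply(rmat, 1, max) + apply(rmat, 1, min)) / 2
  vals <- flow$tau_elem[we] * R / rmid
  sum(vals * mesh$face_area[wf]) / sum(mesh$face_area[wf])
}

#' Split the steady flow residual into Navier-Stokes and porosity parts
#'
#' R1 is the nodal residual of the Navier-Stokes operator without porosity
#' (-u.grad u - grad p / rho + (mu/rho) lap u); R2 = -(pi/rho) phi u is the
#' porosity contribution. Used by the coupling driver's re-solve bookkeeping.
#'
#' @param flow a `flow_state`
#' @param mesh a `tet_mesh`
#' @param fp [fluid_properties]
#' @param pp [porosity_params]
#' @param Cfb per-element bounded fibrin (uM)
#' @param ops optional cached operators
#' @return list with nodal matrices `R1`, `R2` (m/s^2)
#' @export
flow_residual_split <- function(flow, mesh, fp, pp, Cfb, ops = NULL) {
  if (is.null(ops)) ops <- flow_operators(mesh)
  u <- flow$u; p <- flow$p
  nn <- ops$nn
  if (length(Cfb) == 1L) Cfb <- rep(Cfb, ops$ne)
  phi <- hill(Cfb / pp$Cfb0, pp$n_hill)
  ue <- cbind(as.numeric(ops$E2N %*% u[, 1]), as.numeric(ops$E2N %*% u[, 2]),
              as.numeric(ops$E2N %*% u[, 3]))
  Kmu <- .assemble_stiffness(ops, rep(fp$mu, ops$ne))
  R1 <- matrix(0, nn, 3L)
  for (cmp in 1:3) {
    adv_e <- ue[, 1] * as.numeric(ops$Gx %*% u[, cmp]) +
             ue[, 2] * as.numeric(ops$Gy %*% u[, cmp]) +
             ue[, 3] * as.numeric(ops$Gz %*% u[, cmp])
    gpe <- switch(cmp, as.numeric(ops$Gx %*% p), as.numeric(ops$Gy %*% p),
                  as.numeric(ops$Gz %*% p))
    R1[, cmp] <- (-as.numeric(ops$S %*% (adv_e + gpe / fp$rho)) -
                    as.numeric(Kmu %*% u[, cmp]) / fp$rho) / ops$ML
  }
  pc_node <- as.numeric(ops$S %*% (pp$pi_coeff * phi)) / ops$ML
  R2 <- -pc_node / fp$rho * u
  list(R1 = R1, R2 = R2)
}
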