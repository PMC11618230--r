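# Cell-centered finite-volume transport of the six species on a frozen flow
# field. Convective fluxes are first-order upwind by default (optionally
# MUSCL/minmod TVD); diffusive fluxes are central (two-point, face-normal);
# a divergence source C_k Q_k absorbs the residual non-solenoidality of the
# interpolated face velocities. The bounded species Fb has no convective or
# diffusive fluxes and no divergence source; its adhesion reaction sees the
# fibre-length neighbourhood average of C_Fb.

#' Transport solver configuration
#'
#' @param courant Courant factor (0, 1) applied to the stability-limited step
#' @param scheme "upwind1" (monotone, default) or "tvd" (MUSCL with minmod)
#' @param rk_stages 1 (Euler) or 2 (explicit midpoint)
#' @param fiber_length neighbourhood-average radius for bounded fibrin (m)
#' @param dt_cap upper bound on the timestep (s)
#' @param wire_shear_delta pore half-width (m) of the wire-scale shear
#'   closure: inside wire-containing cells the shear seen by the reactions is
#'   max(resolved tau, mu |u| / delta), the near-wire shear that coarse cells
#'   cannot resolve; 0 disables the closure
#' @return list of class `transport_config`
#' @export
transport_config <- function(courant = 0.5, scheme = c("upwind1", "tvd"),
                             rk_stages = 2L, fiber_length = 4e-5,
                             dt_cap = Inf, wire_shear_delta = 1e-4) {
  scheme <- match.arg(scheme)
  stopifnot(courant > 0, courant < 1, rk_stages %in% c(1L, 2L))
  structure(list(courant = courant, scheme = scheme,
                 rk_stages = as.integer(rk_stages),
                 fiber_length = fiber_length, dt_cap = dt_cap,
                 wire_shear_delta = wire_shear_delta),
            class = "transport_config")
}

#' Wire-scale effective shear for the reaction terms
#'
#' Coarse cells cannot resolve the shear at the wire surfaces; within cells
#' that contain wires (distance field below `r0`) the effective shear is the
#' larger of the resolved cell shear and the pore-scale estimate
#' mu |u| / delta. Elsewhere the resolved shear is used unchanged.
#'
#' @param tau_elem resolved per-element shear (Pa)
#' @param u_speed per-element velocity magnitude (m/s)
#' @param r_field per-element distance to the wire surface (m)
#' @param r0 wire-proximity threshold (m)
#' @param mu dynamic viscosity (Pa s)
#' @param delta pore half-width (m); 0 returns `tau_elem`
#' @return effective shear (Pa)
#' @export
wire_scale_shear <- function(tau_elem, u_speed, r_field, r0, mu, delta) {
  if (delta <= 0) return(tau_elem)
  pmax(tau_elem, ifelse(r_field < r0, mu * u_speed / delta, 0))
}

#' Precompute transport operators for a mesh
#'
#' Builds the element-face incidence matrix (with outward sign), face
#' classifications (interior / inlet / outlet / wall+wire-blocked), the
#' diffusive geometric coefficient A/ds per interior face, the bounded-fibrin
#' neighbourhood averaging matrix, and (for the TVD scheme) least-squares
#' cell-gradient operators.
#'
#' @param mesh a `tet_mesh`
#' @param ib optional `immersed_boundary`; faces whose three nodes lie inside
#'   a wire are flux-blocked, and `r_field` is taken from it
#' @param cfg [transport_config]
#' @param need_gradients build TVD gradient operators (automatic for scheme
#'   "tvd")
#' @return list of transport operators (class `transport_ops`)
#' @export
transport_operators <- function(mesh, ib = NULL, cfg = transport_config(),
                                need_gradients = (cfg$scheme == "tvd")) {
  nf <- length(mesh$face_area); ne <- nrow(mesh$tets)
  k1 <- mesh$face_k1; k2 <- mesh$face_k2
  interior <- which(!is.na(k2))
  blocked <- logical(nf)
  if (!is.null(ib) && any(is.finite(ib$node_dist))) {
    nd <- ib$node_dist
    blocked <- nd[mesh$face_nodes[, 1]] < 0 & nd[mesh$face_nodes[, 2]] < 0 &
      nd[mesh$face_nodes[, 3]] < 0
  }
  inlet <- which(mesh$face_tag == 1L & !blocked)
  outlet <- which(mesh$face_tag == 2L & !blocked)
  flux_faces <- c(interior[!blocked[interior]], inlet, outlet)

  ii <- c(k1, k2[interior])
  jj <- c(seq_len(nf), interior)
  xx <- c(rep(1, nf), rep(-1, length(interior)))
  T <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ne, nf))
  # unsigned incidence matrices for the per-element outflux CFL bound
  Tk1 <- Matrix::sparseMatrix(i = k1, j = seq_len(nf), x = rep(1, nf),
                              dims = c(ne, nf))
  Tk2 <- Matrix::sparseMatrix(i = k2[interior], j = interior,
                              x = rep(1, length(interior)), dims = c(ne, nf))

  cD <- numeric(nf)
  cD[interior] <- mesh$face_area[interior] / mesh$face_ds[interior]
  cD[blocked] <- 0

  W <- neighbor_average_matrix(mesh, cfg$fiber_length)
  r_field <- if (!is.null(ib)) ib$r_field else rep(Inf, ne)

  ops <- list(ne = ne, nf = nf, k1 = k1, k2 = k2, interior = interior,
              inlet = inlet, outlet = outlet, blocked = blocked,
              flux_interior = interior[!blocked[interior]],
              T = T, Tk1 = Tk1, Tk2 = Tk2,
              cD = cD, W = W, r_field = r_field,
              V = mesh$V, h = mesh$h, tets = mesh$tets,
              elem_face = mesh$elem_face, centroid = mesh$centroid,
              face_area = mesh$face_area, face_normal = mesh$face_normal,
              face_nodes = mesh$face_nodes)
  if (need_gradients) ops$grad <- .cell_gradient_ops(mesh)
  class(ops) <- "transport_ops"
  ops
}

# least-squares cell gradients from face-neighbour centroid differences
.cell_gradient_ops <- function(mesh) {
  interior <- which(!is.na(mesh$face_k2))
  k1 <- mesh$face_k1[interior]; k2 <- mesh$face_k2[interior]
  ne <- nrow(mesh$tets)
  e_from <- c(k1, k2); e_to <- c(k2, k1)
  dx <- mesh$centroid[e_to, , drop = FALSE] - mesh$centroid[e_from, , drop = FALSE]
  # per-element normal matrix N = sum dx dx^T; gradient = N^-1 sum dx dC
  idx <- sort(unique(e_from))
  accm <- matrix(0, ne, 6L)  # xx, yy, zz, xy, xz, yz
  comp <- cbind(dx[, 1]^2, dx[, 2]^2, dx[, 3]^2,
                dx[, 1] * dx[, 2], dx[, 1] * dx[, 3], dx[, 2] * dx[, 3])
  for (c6 in 1:6) accm[idx, c6] <- as.numeric(rowsum(comp[, c6], e_from))
  # invert symmetric 3x3 per element (adjugate)
  a <- accm[, 1]; b <- accm[, 4]; c3 <- accm[, 5]
  d <- accm[, 2]; e <- accm[, 6]; f <- accm[, 3]
  det <- a * (d * f - e^2) - b * (b * f - e * c3) + c3 * (b * e - d * c3)
  det[abs(det) < 1e-300] <- Inf   # degenerate (isolated) elements: zero grad
  inv <- cbind((d * f - e^2), (c3 * e - b * f), (b * e - c3 * d),
               (a * f - c3^2), (b * c3 - a * e), (a * d - b^2)) / det
  # weights for each neighbour pair: w = N^-1 dx  (rows of a sparse op)
  wx <- inv[e_from, 1] * dx[, 1] + inv[e_from, 2] * dx[, 2] + inv[e_from, 3] * dx[, 3]
  wy <- inv[e_from, 2] * dx[, 1] + inv[e_from, 4] * dx[, 2] + inv[e_from, 5] * dx[, 3]
  wz <- inv[e_from, 3] * dx[, 1] + inv[e_from, 5] * dx[, 2] + inv[e_from, 6] * dx[, 3]
  # gradient_x(C) = sum_nb wx * (C_nb - C_self) -> sparse matrix form
  Gx <- Matrix::sparseMatrix(i = c(e_from, e_from), j = c(e_to, e_from),
                             x = c(wx, -wx), dims = c(ne, ne))
  Gy <- Matrix::sparseMatrix(i = c(e_from, e_from), j = c(e_to, e_from),
                             x = c(wy, -wy), dims = c(ne, ne))
  Gz <- Matrix::sparseMatrix(i = c(e_from, e_from), j = c(e_to, e_from),
                             x = c(wz, -wz), dims = c(ne, ne))
  list(Gx = Gx, Gy = Gy, Gz = Gz)
}

#' Neighbourhood averaging matrix for bounded fibrin
#'
#' Sparse row-stochastic matrix whose k-th row averages element k and all
#' elements whose centroids lie within `fiber_length` of k's centroid
#' (arithmetic mean; equals the identity when `fiber_length = 0`).
#'
#' @param mesh a `tet_mesh`
#' @param fiber_length radius (m)
#' @return sparse ne x ne matrix
#' @export
neighbor_average_matrix <- function(mesh, fiber_length) {
  ne <- nrow(mesh$tets)
  if (fiber_length <= 0) return(Matrix::Diagonal(ne))
  cc <- mesh$centroid
  cell <- max(fiber_length, 1e-12)
  lo <- apply(cc, 2, min) - 1e-12
  ij <- floor(sweep(cc, 2, lo) / cell)
  dims <- apply(ij, 2, max) + 2L
  key <- ij[, 1] + dims[1] * (ij[, 2] + dims[2] * ij[, 3])
  members <- split(seq_len(ne), key)
  pairs_i <- vector("list", 27L); pairs_j <- vector("list", 27L)
  n27 <- 0L
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    tkey <- (ij[, 1] + ox) + dims[1] * ((ij[, 2] + oy) + dims[2] * (ij[, 3] + oz))
    tgt <- members[as.character(tkey)]
    len <- lengths(tgt)
    if (!sum(len)) next
    n27 <- n27 + 1L
    pairs_i[[n27]] <- rep.int(seq_len(ne), len)
    pairs_j[[n27]] <- unlist(tgt, use.names = FALSE)
  }
  i <- unlist(pairs_i[seq_len(n27)], use.names = FALSE)
  j <- unlist(pairs_j[seq_len(n27)], use.names = FALSE)
  d2 <- (cc[i, 1] - cc[j, 1])^2 + (cc[i, 2] - cc[j, 2])^2 +
        (cc[i, 3] - cc[j, 3])^2
  keep <- d2 <= fiber_length^2
  i <- i[keep]; j <- j[keep]
  cnt <- tabulate(i, nbins = ne)
  Matrix::sparseMatrix(i = i, j = j, x = 1 / cnt[i], dims = c(ne, ne))
}

#' Neighbourhood-averaged bounded fibrin
#'
#' @param Cfb per-element bounded fibrin (uM)
#' @param mesh a `tet_mesh`
#' @param fiber_length radius (m)
#' @export
bounded_neighbor_average <- function(Cfb, mesh, fiber_length) {
  as.numeric(neighbor_average_matrix(mesh, fiber_length) %*% Cfb)
}

#' Attach a frozen flow field to the transport operators
#'
#' Computes the face-normal volumetric fluxes u_j . n_j A_j (face velocity =
#' arithmetic mean of the three face-node velocities), the element divergence
#' Q_k, upwind element indices per face, and stores the element speeds and
#' shear used by the timestep bound and the reaction terms.
#'
#' @param ops `transport_ops`
#' @param u nodal velocity (n_nodes x 3), or NULL when `un_A` given directly
#' @param tau_elem per-element shear magnitude (Pa)
#' @param un_A optional per-face normal flux (m^3/s), overrides `u`
#' @param p optional [reaction_params]; when given, the reaction switch
#'   functions (wire proximity, shear) are precomputed here and reused by
#'   [transport_step] and [stable_dt]
#' @return updated `transport_ops` with flow attached
#' @export
transport_set_flow <- function(ops, u = NULL, tau_elem = 0, un_A = NULL,
                               p = NULL) {
  if (is.null(un_A)) {
    fn <- ops$face_nodes
    uf <- (u[fn[, 1], , drop = FALSE] + u[fn[, 2], , drop = FALSE] +
           u[fn[, 3], , drop = FALSE]) / 3
    un_A <- rowSums(uf * ops$face_normal) * ops$face_area
  }
  un_A[ops$blocked] <- 0
  # walls (any boundary face that is neither inlet nor outlet): no flux
  bdry <- which(is.na(ops$k2))
  un_A[setdiff(bdry, c(ops$inlet, ops$outlet))] <- 0
  Q <- as.numeric(ops$T %*% un_A)
  up <- ops$k1
  ii <- ops$flux_interior
  up[ii] <- ifelse(un_A[ii] >= 0, ops$k1[ii], ops$k2[ii])
  # inlet faces with inflow take the prescribed value (marked 0)
  up[ops$inlet][un_A[ops$inlet] < 0] <- 0L
  ops$un_A <- un_A; ops$Q <- Q; ops$upwind <- up
  # total positive outward flux per element: the rigorous upwind CFL scale,
  # robust for anisotropic cells (h/|u| alone is not)
  ops$outflux <- as.numeric(ops$Tk1 %*% pmax(un_A, 0)) +
    as.numeric(ops$Tk2 %*% pmax(-un_A, 0))
  if (!is.null(u)) {
    spd <- sqrt(rowSums(u^2))   # element speed = mean of the four node speeds
    t4 <- ops$tets
    ops$u_elem <- (spd[t4[, 1]] + spd[t4[, 2]] + spd[t4[, 3]] + spd[t4[, 4]]) / 4
  } else {
    # face-flux-based estimate: max normal speed over the element's faces
    fspeed <- abs(un_A) / ops$face_area
    ops$u_elem <- pmax(fspeed[ops$elem_face[, 1]], fspeed[ops$elem_face[, 2]],
                       fspeed[ops$elem_face[, 3]], fspeed[ops$elem_face[, 4]])
  }
  ops$tau_elem <- if (length(tau_elem) == 1L) rep(tau_elem, ops$ne) else tau_elem
  if (!is.null(p)) {
    ops$switches <- list(
      w = wire_proximity_switch(ops$r_field, p$r0, p$n_hill,
                                literal = p$wire_switch_literal),
      sw_tau = hill(ops$tau_elem / p$tau0, p$n_hill))
  }
  ops
}

#' Per-face convective and diffusive fluxes
#'
#' Returns per-face fluxes (uM m^3/s), positive out of element k1. Interior
#' faces: upwind convective flux and central diffusive flux with the
#' face-average diffusivity. Inlet faces carry only the convective flux with
#' the prescribed upstream concentration; outlet faces the convective flux
#' with the interior concentration; wall and wire-blocked faces carry zero
#' flux. The bounded species Fb carries no fluxes at all.
#'
#' @param ops `transport_ops` with flow attached ([transport_set_flow])
#' @param C concentration matrix (ne x 6), columns in [SPECIES] order
#' @param D per-species diffusivities ([species_diffusivities])
#' @param inlet_values named 6-vector of inlet concentrations (uM)
#' @param cfg [transport_config]
#' @return list with matrices `conv` and `diff` (nf x 6)
#' @export
face_fluxes <- function(ops, C, D, inlet_values, cfg = transport_config()) {
  nf <- ops$nf
  conv <- matrix(0, nf, 6L)
  diffm <- matrix(0, nf, 6L)
  act <- c(ops$flux_interior, ops$inlet, ops$outlet)
  up <- ops$upwind[act]
  ext <- up == 0L                      # prescribed inlet value
  Cface <- matrix(0, length(act), 6L)
  Cface[!ext, ] <- C[up[!ext], , drop = FALSE]
  if (any(ext)) Cface[ext, ] <- matrix(inlet_values[SPECIES],
                                       sum(ext), 6L, byrow = TRUE)
  if (cfg$scheme == "tvd" && !is.null(ops$grad)) {
    Cface <- .tvd_correct(ops, C, Cface, act, ext)
  }
  conv[act, ] <- ops$un_A[act] * Cface
  ii <- ops$flux_interior
  dC <- C[ops$k1[ii], , drop = FALSE] - C[ops$k2[ii], , drop = FALSE]
  diffm[ii, ] <- (ops$cD[ii] * dC) * rep(D[SPECIES], each = length(ii))
  conv[, 6L] <- 0; diffm[, 6L] <- 0    # bounded fibrin is not transported
  list(conv = conv, diff = diffm)
}

# MUSCL linear reconstruction with minmod limiting on interior faces:
# C_f = C_up + 1/2 minmod(delta_centered, delta_upwind) where
# delta_centered = C_dn - C_up and delta_upwind = 2 gradC_up.(x_dn - x_up)
# - delta_centered (the face is taken halfway between the centroids).
.tvd_correct <- function(ops, C, Cface, act, ext) {
  ii <- ops$flux_interior
  nii <- length(ii)
  pos <- ops$un_A[ii] >= 0
  upc <- ifelse(pos, ops$k1[ii], ops$k2[ii])
  dnc <- ifelse(pos, ops$k2[ii], ops$k1[ii])
  dxc <- ops$centroid[dnc, , drop = FALSE] - ops$centroid[upc, , drop = FALSE]
  minmod <- function(a, b) 0.5 * (sign(a) + sign(b)) * pmin(abs(a), abs(b))
  # positions of the interior faces within `act` (they come first)
  for (s in 1:5) {
    gx <- as.numeric(ops$grad$Gx %*% C[, s])
    gy <- as.numeric(ops$grad$Gy %*% C[, s])
    gz <- as.numeric(ops$grad$Gz %*% C[, s])
    d_c <- C[dnc, s] - C[upc, s]
    gproj <- gx[upc] * dxc[, 1] + gy[upc] * dxc[, 2] + gz[upc] * dxc[, 3]
    d_u <- 2 * gproj - d_c
    Cface[seq_len(nii), s] <- C[upc, s] + 0.5 * minmod(d_c, d_u)
  }
  Cface
}

#' Stability-limited transport timestep
#'
#' dt = courant * min over elements/species of the convection bound h/|u|,
#' the diffusion bound h^2/(2D), the divergence bound V/Q (for Q > 0) and
#' the reaction bound min_i C_i/|S_i| (local linearized sink time), capped
#' at `cfg$dt_cap`.
#'
#' @param ops `transport_ops` with flow attached
#' @param C concentration matrix (ne x 6)
#' @param D per-species diffusivities
#' @param p [reaction_params]
#' @param cfg [transport_config]
#' @param Cfb_avg optional precomputed neighbourhood-averaged bounded fibrin
#' @return dt (s)
#' @export
stable_dt <- function(ops, C, D, p, cfg = transport_config(), Cfb_avg = NULL) {
  bounds <- cfg$dt_cap
  spd <- ops$u_elem
  if (any(spd > 0)) bounds <- min(bounds, min(ops$h[spd > 0] / spd[spd > 0]))
  opos <- ops$outflux > 0
  if (any(opos)) bounds <- min(bounds, min(ops$V[opos] / ops$outflux[opos]))
  Dmax <- max(D[SPECIES[1:5]])
  if (Dmax > 0) bounds <- min(bounds, min(ops$h^2) / (2 * Dmax))
  qpos <- ops$Q > 0
  if (any(qpos)) bounds <- min(bounds, min(ops$V[qpos] / ops$Q[qpos]))
  if (is.null(Cfb_avg)) Cfb_avg <- as.numeric(ops$W %*% C[, 6L])
  S <- source_terms(C, ops$tau_elem, ops$r_field, Cfb_avg, p,
                    switches = ops$switches)
  # linearized sink time C_i/|S_i| where S_i is a net sink (for a linear sink
  # -k C this is 1/k, independent of C); production does not limit stability
  act <- C > 1e-12 & S < 0
  if (any(act)) bounds <- min(bounds, min(C[act] / (-S[act])))
  dt <- cfg$courant * bounds
  if (!is.finite(dt) || dt <= 0)
    stop("stable_dt: no finite positive timestep (empty constraints and no cap?)")
  dt
}

#' Advance the species field by one explicit Runge-Kutta step
#'
#' @param ops `transport_ops` with flow attached
#' @param C concentration matrix (ne x 6)
#' @param D per-species diffusivities
#' @param p [reaction_params]
#' @param inlet_values named 6-vector (uM)
#' @param dt timestep (s)
#' @param cfg [transport_config]
#' @param react include reaction sources (FALSE gives pure transport)
#' @param Cfb_avg1 optional precomputed neighbourhood average for the first
#'   stage (shared with [stable_dt] when both are called on the same state)
#' @return list with updated `C` and `clipped` mass (uM, summed over stages)
#' @export
transport_step <- function(ops, C, D, p, inlet_values, dt,
                           cfg = transport_config(), react = TRUE,
                           Cfb_avg1 = NULL) {
  clipped <- 0
  rhs <- function(Cm, cavg) {
    fl <- face_fluxes(ops, Cm, D, inlet_values, cfg)
    out <- -as.matrix(ops$T %*% (fl$conv + fl$diff))
    out <- out + Cm * ops$Q
    out[, 6L] <- out[, 6L] - Cm[, 6L] * ops$Q   # no divergence source for Fb
    if (react) {
      if (is.null(cavg)) cavg <- as.numeric(ops$W %*% Cm[, 6L])
      S <- source_terms(Cm, ops$tau_elem, ops$r_field, cavg, p,
                        switches = ops$switches)
      out <- out + S * ops$V
    }
    out / ops$V
  }
  clip <- function(Cm) {
    neg <- Cm < 0
    if (any(neg)) { clipped <<- clipped + sum(-Cm[neg]); Cm[neg] <- 0 }
    Cm
  }
  if (cfg$rk_stages == 1L) {
    C <- clip(C + dt * rhs(C, Cfb_avg1))
  } else {
    Cmid <- clip(C + dt / 2 * rhs(C, Cfb_avg1))
    C <- clip(C + dt * rhs(Cmid, NULL))
  }
  if (anyNA(C) || any(!is.finite(C))) {
    bad <- which(!is.finite(C), arr.ind = TRUE)[1, ]
    stop(sprintf("transport blow-up at element %d species %s",
                 bad[1], SPECIES[bad[2]]))
  }
  list(C = C, clipped = clipped)
}
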