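# Structured generators. Hexahedral blocks are split into 6 tets per cube via
# the Kuhn (Freudenthal) template around the main diagonal; because every cube
# uses the same template, face diagonals match across shared faces and the
# triangulation is conforming.

.KUHN <- rbind(  # 6 tets as corner-offset indices into the 8 cube corners
  c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
  c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))
# corner order: (i,j,k) bits -> 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0)
#               5:(0,0,1) 6:(1,0,1) 7:(0,1,1) 8:(1,1,1)

.cube_corner_offsets <- cbind(
  i = c(0, 1, 0, 1, 0, 1, 0, 1),
  j = c(0, 0, 1, 1, 0, 0, 1, 1),
  k = c(0, 0, 0, 0, 1, 1, 1, 1))

# Tetrahedralize a set of unit cubes on an (nx+1)x(ny+1)x(nz+1) node lattice.
# cubes: matrix of (i,j,k) zero-based cube indices. Returns list(nodes_idx
# used lattice node ids in original numbering, tets re-indexed to those).
.cubes_to_tets <- function(cubes, nx, ny, nz) {
  nnx <- nx + 1L; nny <- ny + 1L
  node_id <- function(i, j, k) 1L + i + nnx * (j + nny * k)
  nc <- nrow(cubes)
  corner <- matrix(0L, nc, 8L)
  for (c8 in 1:8) {
    off <- .cube_corner_offsets[c8, ]
    corner[, c8] <- node_id(cubes[, 1] + off[1], cubes[, 2] + off[2],
                            cubes[, 3] + off[3])
  }
  tets <- matrix(0L, 6L * nc, 4L)
  for (t6 in 1:6) {
    tets[seq.int(t6, by = 6L, length.out = nc), ] <-
      corner[, .KUHN[t6, ], drop = FALSE]
  }
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nnx * nny * (nz + 1L))
  remap[used] <- seq_along(used)
  tets[] <- remap[tets]
  list(node_ids = used, tets = tets)
}

#' Structured tetrahedral box mesh
#'
#' Axis-aligned box `[0,lx] x [0,ly] x [0,lz]` split into `nx*ny*nz` cubes of
#' 6 tets each. Boundary tags: x = 0 inlet, x = lx outlet, rest wall.
#'
#' @param lx,ly,lz box dimensions (m)
#' @param nx,ny,nz cell counts per direction
#' @return a `tet_mesh`
#' @export
generate_box_mesh <- function(lx, ly, lz, nx, ny, nz) {
  stopifnot(lx > 0, ly > 0, lz > 0, nx >= 1, ny >= 1, nz >= 1)
  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  nodes <- cbind(g$i * (lx / nx), g$j * (ly / ny), g$k * (lz / nz))
  cubes <- as.matrix(expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1)))
  ct <- .cubes_to_tets(cubes, nx, ny, nz)
  tol <- 1e-9 * max(lx, ly, lz)
  classify <- function(fc, fn) {
    ifelse(fc[, 1] < tol, 1L, ifelse(fc[, 1] > lx - tol, 2L, 3L))
  }
  build_tet_mesh(nodes[ct$node_ids, , drop = FALSE], ct$tets, classify,
                 geom = list(type = "box", lx = lx, ly = ly, lz = lz))
}

# elliptic square -> unit disc map; (s,t) in [-1,1]^2, boundary -> unit circle
.disc_map <- function(s, t) {
  cbind(s * sqrt(1 - t^2 / 2), t * sqrt(1 - s^2 / 2))
}

#' Tetrahedral mesh of a circular tube
#'
#' Body-fitted cylinder mesh: an n x n structured square cross-section is
#' mapped onto the disc with the elliptic map (all boundary nodes land
#' exactly on the circle) and extruded along +x, then split into tets.
#' Tags: inlet at x = 0, outlet at x = length, lateral wall. Flow axis = +x.
#'
#' @param diameter tube diameter (m)
#' @param length tube length (m)
#' @param target_h target element size (m); must be < diameter/4
#' @param axial_stretch axial spacing as a multiple of `target_h` (the flow
#'   is axis-aligned, so mild axial anisotropy is harmless)
#' @param wall_grading radial exponent < 1 clusters nodes towards the wall
#'   (1 = uniform)
#' @return a `tet_mesh` with `geom` describing the analytic cylinder
#' @export
generate_tube_mesh <- function(diameter, length, target_h,
                               axial_stretch = 2, wall_grading = 1) {
  if (target_h >= diameter / 4)
    stop("generate_tube_mesh: target_h must be < diameter/4 (got target_h = ",
         target_h, ", diameter = ", diameter, ")")
  R <- diameter / 2
  n <- max(4L, as.integer(ceiling(diameter / target_h)))
  nz <- max(2L, as.integer(ceiling(length / (axial_stretch * target_h))))
  sv <- seq(-1, 1, length.out = n + 1L)
  g <- expand.grid(s = sv, t = sv)
  yz <- .disc_map(g$s, g$t)
  if (wall_grading != 1) {
    rr <- sqrt(rowSums(yz^2))
    scale <- ifelse(rr > 0, rr^(wall_grading - 1), 1)
    yz <- yz * scale
  }
  yz <- yz * R
  xs <- seq(0, length, length.out = nz + 1L)
  nn2 <- nrow(yz)
  # lattice ordering must match .cubes_to_tets: id = 1 + i + (n+1)*(j + (n+1)*k)
  # with i <-> s index (fastest, as produced by expand.grid), j <-> t, k axial
  nodes <- matrix(0, nn2 * (nz + 1L), 3L)
  idx <- 1L
  for (k in 0:nz) {
    nodes[idx:(idx + nn2 - 1L), ] <- cbind(xs[k + 1L], yz)
    idx <- idx + nn2
  }
  cubes <- as.matrix(expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(nz - 1)))
  ct <- .cubes_to_tets(cubes, n, n, nz)
  tol_x <- 1e-9 * length
  classify <- function(fc, fn) {
    ifelse(fc[, 1] < tol_x, 1L, ifelse(fc[, 1] > length - tol_x, 2L, 3L))
  }
  build_tet_mesh(nodes[ct$node_ids, , drop = FALSE], ct$tets, classify,
                 geom = list(type = "tube", diameter = diameter,
                             length = length, radius = R, axis = "x"))
}

# --- sidewall aneurysm: implicit geometry -----------------------------------

# geometry helper: distance to the curved-vessel centerline and arc angle.
# Centerline: circle of radius Rc centered at (0, -Rc, 0) in the z = 0 plane
# (passes through the origin with tangent +x); straight variant along x when
# Rc = Inf.
.vessel_coords <- function(p, Rc) {
  if (is.infinite(Rc)) {
    list(d = sqrt(p[, 2]^2 + p[, 3]^2), s = p[, 1])   # s = arclength
  } else {
    rho <- sqrt(p[, 1]^2 + (p[, 2] + Rc)^2)
    theta <- atan2(p[, 1], p[, 2] + Rc)
    list(d = sqrt((rho - Rc)^2 + p[, 3]^2), s = theta * Rc)
  }
}

#' Tetrahedral mesh of an idealized sidewall aneurysm
#'
#' A curved parent vessel (torus-segment tube of diameter `vessel_d` whose
#' centerline has radius of curvature `curvature_radius`; straight when
#' `curvature_radius = Inf`) unioned with a spherical sac of diameter
#' `aneurysm_d` seated on the outer bend. The sphere centre height above the
#' centerline is chosen so the sac opening at the vessel surface has diameter
#' `neck_d`. The mesh is an implicit-geometry Cartesian voxel-tet mesh: cells
#' whose centre lies inside the union are kept and split into tets (the
#' boundary is therefore stair-stepped at the voxel scale).
#'
#' The analytic neck-plane disc (centre, normal, radius) is stored in `geom`
#' for inflow metrics, together with the sac sphere.
#'
#' @param vessel_d parent-vessel internal diameter (m)
#' @param aneurysm_d sac diameter (m)
#' @param curvature_radius centerline radius of curvature (m); `Inf` gives a
#'   straight vessel
#' @param neck_d neck diameter (m); must be <= aneurysm_d
#' @param target_h voxel size (m)
#' @param vessel_length centerline length (m)
#' @return a `tet_mesh`
#' @export
generate_sidewall_aneurysm_mesh <- function(vessel_d, aneurysm_d,
                                            curvature_radius, neck_d = vessel_d,
                                            target_h,
                                            vessel_length = 6 * vessel_d) {
  if (neck_d > aneurysm_d) stop("neck_d must be <= aneurysm_d")
  if (target_h >= vessel_d / 4) stop("target_h must be < vessel_d/4")
  rv <- vessel_d / 2; rs <- aneurysm_d / 2; rn <- neck_d / 2
  Rc <- curvature_radius
  hc <- rv + sqrt(rs^2 - rn^2)          # sac centre height above centerline
  sac_center <- c(0, hc, 0)
  half_len <- vessel_length / 2

  # bounding box of the union (origin = neck point on the centerline)
  if (is.infinite(Rc)) {
    xr <- c(-half_len, half_len)
    yr <- c(-rv, hc + rs)
  } else {
    th <- half_len / Rc
    xr <- c(-(Rc + rv) * sin(th), (Rc + rv) * sin(th))
    ylow <- (Rc - rv) * cos(th) - Rc    # inner wall at the arc ends
    yr <- c(min(-rv, ylow) , hc + rs)
  }
  zr <- c(-max(rv, rs), max(rv, rs))
  pad <- target_h
  xr <- xr + c(-pad, pad); yr <- yr + c(-pad, pad); zr <- zr + c(-pad, pad)
  nx <- as.integer(ceiling(diff(xr) / target_h))
  ny <- as.integer(ceiling(diff(yr) / target_h))
  nzc <- as.integer(ceiling(diff(zr) / target_h))
  hx <- diff(xr) / nx; hy <- diff(yr) / ny; hz <- diff(zr) / nzc

  cc <- as.matrix(expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nzc - 1)))
  centers <- cbind(xr[1] + (cc[, 1] + 0.5) * hx,
                   yr[1] + (cc[, 2] + 0.5) * hy,
                   zr[1] + (cc[, 3] + 0.5) * hz)
  vc <- .vessel_coords(centers, Rc)
  in_vessel <- vc$d <= rv & abs(vc$s) <= half_len
  in_sac <- sqrt(rowSums(sweep(centers, 2, sac_center)^2)) <= rs
  keep <- in_vessel | in_sac
  if (!any(keep)) stop("empty sidewall mesh: check dimensions")
  cubes <- cc[keep, , drop = FALSE]
  ct <- .cubes_to_tets(cubes, nx, ny, nzc)
  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nzc)
  lattice_nodes <- cbind(xr[1] + g$i * hx, yr[1] + g$j * hy, zr[1] + g$k * hz)

  smax <- half_len - 0.75 * target_h    # faces beyond this arclength are ends
  classify <- function(fc, fn) {
    v <- .vessel_coords(fc, Rc)
    tg <- rep(3L, nrow(fc))
    # all boundary faces in the end zones belong to the (stair-stepped)
    # inlet/outlet surfaces; tagging them all avoids spurious no-slip
    # constrictions across the ragged end planes
    ends <- abs(v$s) > smax & v$d <= rv + 1e-12
    tg[ends & v$s < 0] <- 1L
    tg[ends & v$s > 0] <- 2L
    tg
  }
  geom <- list(type = "sidewall", vessel_d = vessel_d, aneurysm_d = aneurysm_d,
               curvature_radius = Rc, neck_d = neck_d,
               vessel_length = vessel_length,
               sac_center = sac_center, sac_radius = rs,
               neck_plane = list(center = c(0, rv, 0), normal = c(0, 1, 0),
                                 radius = rn))
  build_tet_mesh(lattice_nodes[ct$node_ids, , drop = FALSE], ct$tets,
                 classify, geom = geom)
}

#' Distance to the vessel centerline and arclength coordinate
#'
#' For tube meshes the centerline is the x axis; for sidewall meshes it is
#' the (possibly curved) parent-vessel centerline. Used to impose parabolic
#' inlet profiles and to locate the neck.
#'
#' @param mesh a `tet_mesh` with geom type "tube" or "sidewall"
#' @param p points (n x 3)
#' @return list with `d` (radial distance, m) and `s` (arclength along the
#'   centerline, m) and `tangent` (n x 3 local flow direction)
#' @export
centerline_coords <- function(mesh, p) {
  g <- mesh$geom
  if (identical(g$type, "tube") || identical(g$type, "box")) {
    d <- sqrt(p[, 2]^2 + p[, 3]^2)
    list(d = d, s = p[, 1],
         tangent = matrix(rep(c(1, 0, 0), each = nrow(p)), ncol = 3))
  } else if (identical(g$type, "sidewall")) {
    Rc <- g$curvature_radius
    v <- .vessel_coords(p, Rc)
    if (is.infinite(Rc)) {
      tangent <- matrix(rep(c(1, 0, 0), each = nrow(p)), ncol = 3)
    } else {
      thf <- v$s / Rc
      tangent <- cbind(cos(thf), -sin(thf), 0)
    }
    list(d = v$d, s = v$s, tangent = tangent)
  } else stop("centerline_coords: unsupported geometry type")
}
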