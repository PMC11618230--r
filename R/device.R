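#' Build a braided flow-diverter device (or a flat wire screen)
#'
#' Two constructions are supported:
#' \describe{
#' \item{helical}{the deployed braided stent: `n_wires/2` helices of each
#'   handedness on a cylinder of radius `surface_radius` (optionally swept
#'   along a curved vessel centerline of radius `curvature_radius`). The
#'   braid angle is the angle between crossing wires, so each wire runs at
#'   `braid_angle/2` from the device axis; larger braid angles give more
#'   circumferential wires and smaller pores.}
#' \item{screen}{a flat disc of two crossing wire families perpendicular to
#'   the flow axis (+x), used for the straight-tube benchmark. The cell
#'   internal angle equals `braid_angle` and `cell_side` sets the rhombic
#'   cell side length, so the pore area per cell is `cell_side^2 *
#'   sin(braid_angle)` -- a 150 degree screen has half the pore area of a 90
#'   degree one at equal side length.}
#' }
#'
#' Each wire is returned as a polyline plus a sampling of overlapping spheres
#' (spacing <= sphere radius) used for immersed-boundary edge cutting.
#'
#' @param n_wires number of wires (helical: must be even)
#' @param wire_diameter wire thickness (m)
#' @param braid_angle crossing angle between wire families (degrees, in
#'   (0, 180))
#' @param surface_radius deployment-cylinder radius (helical) or screen disc
#'   radius (screen) (m)
#' @param length device length along the axis (helical) (m)
#' @param type "helical" or "screen"
#' @param curvature_radius centerline curvature radius for curved deployment
#'   (m), `Inf` for a straight cylinder
#' @param center_s arclength position of the device centre along the
#'   centerline (m); for screens, the x position of the disc
#' @param cell_side rhombic cell side length for screens (m)
#' @param seg_length polyline sampling interval (m); default resolves the
#'   helix curvature to well below the wire radius
#' @return object of class `wire_set`
#' @export
build_braided_device <- function(n_wires, wire_diameter, braid_angle,
                                 surface_radius, length = NULL,
                                 type = c("helical", "screen"),
                                 curvature_radius = Inf, center_s = 0,
                                 cell_side = NULL, seg_length = NULL) {
  type <- match.arg(type)
  if (braid_angle <= 0 || braid_angle >= 180)
    stop("braid_angle must be in (0, 180) degrees")
  wr <- wire_diameter / 2
  if (wr <= 0) stop("wire_diameter must be > 0")

  if (type == "helical") {
    if (n_wires %% 2L != 0L) stop("helical devices need an even n_wires")
    if (is.null(length)) stop("helical devices need a length")
    alpha <- (braid_angle / 2) * pi / 180      # wire angle from device axis
    dpsi_ds <- tan(alpha) / surface_radius
    if (is.null(seg_length))
      seg_length <- max(wr, 0.02 * surface_radius / max(tan(alpha), 0.2))
    ns <- max(8L, ceiling(length / seg_length / cos(alpha)) + 1L)
    svals <- seq(center_s - length / 2, center_s + length / 2, length.out = ns)
    nh <- n_wires / 2L
    wires <- vector("list", n_wires)
    for (i in seq_len(nh)) {
      psi0 <- 2 * pi * (i - 1) / nh
      for (hand in c(1, -1)) {
        psi <- psi0 + hand * dpsi_ds * (svals - center_s)
        wires[[(i - 1L) * 2L + (3 - hand) / 2]] <-
          .on_surface(svals, psi, surface_radius, curvature_radius)
      }
    }
  } else {
    # flat screen in the y-z plane at x = center_s
    gam <- braid_angle * pi / 180
    if (is.null(cell_side)) cell_side <- surface_radius / 2
    w <- cell_side * sin(gam)                  # perpendicular wire spacing
    half <- gam / 2
    dirs <- list(c(cos(half), sin(half)), c(cos(half), -sin(half)))
    wires <- list()
    R <- surface_radius
    for (d2 in dirs) {
      nrm <- c(-d2[2], d2[1])
      offs <- seq(-floor(R / w), floor(R / w)) * w
      for (o in offs) {
        half_chord <- sqrt(max(R^2 - o^2, 0))
        if (half_chord < w / 4) next
        tv <- seq(-half_chord, half_chord, length.out =
                    max(2L, ceiling(2 * half_chord / (R / 8)) + 1L))
        yz <- cbind(o * nrm[1] + tv * d2[1], o * nrm[2] + tv * d2[2])
        wires[[length(wires) + 1L]] <- cbind(center_s, yz)
      }
    }
    n_wires <- length(wires)
  }

  spheres <- .sample_spheres(wires, wr)
  structure(list(wires = wires, wire_radius = wr,
                 spheres = spheres, sphere_radius = wr,
                 braid_angle = braid_angle, n_wires = n_wires, type = type,
                 surface_radius = surface_radius, length = length,
                 curvature_radius = curvature_radius, center_s = center_s,
                 cell_side = if (type == "screen") cell_side else NULL),
            class = "wire_set")
}

# map (arclength, around-angle) to 3D on the deployment surface
.on_surface <- function(s, psi, r, Rc) {
  if (is.infinite(Rc)) {
    cbind(s, r * cos(psi), r * sin(psi))
  } else {
    th <- s / Rc
    P <- cbind(Rc * sin(th), Rc * cos(th) - Rc, 0 * th)  # centerline point
    u <- cbind(sin(th), cos(th), 0 * th)                 # outward radial
    P + r * (cos(psi) * u + cbind(0 * psi, 0 * psi, sin(psi)))
  }
}

.sample_spheres <- function(wires, radius, spacing_factor = 0.9) {
  centers <- lapply(wires, function(w) {
    seg <- diff(w)
    len <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(len))
    total <- cum[length(cum)]
    if (total == 0) return(w[1, , drop = FALSE])
    sp <- spacing_factor * radius
    tv <- seq(0, total, by = sp)
    idx <- findInterval(tv, cum, rightmost.closed = TRUE)
    idx[idx >= nrow(w)] <- nrow(w) - 1L
    frac <- (tv - cum[idx]) / pmax(len[idx], .Machine$double.eps)
    w[idx, , drop = FALSE] + frac * (w[idx + 1L, , drop = FALSE] -
                                     w[idx, , drop = FALSE])
  })
  list(centers = do.call(rbind, centers), radius = radius)
}

#' @export
print.wire_set <- function(x, ...) {
  cat("wire_set (", x$type, "): ", x$n_wires, " wires, radius ",
      format(x$wire_radius, digits = 3), " m, braid angle ", x$braid_angle,
      " deg, ", nrow(x$spheres$centers), " spheres\n", sep = "")
  invisible(x)
}

#' All wire polyline segments as parallel start/end matrices
#' @param ws a `wire_set`
#' @return list with matrices `a` and `b` (n_seg x 3)
#' @export
wire_segments <- function(ws) {
  a <- do.call(rbind, lapply(ws$wires, function(w) w[-nrow(w), , drop = FALSE]))
  b <- do.call(rbind, lapply(ws$wires, function(w) w[-1L, , drop = FALSE]))
  list(a = a, b = b)
}

#' Restrict a deployed device to its orifice-spanning portion
#'
#' Wire segments apposed to the parent-vessel wall sit inside the (coarse,
#' unresolved) near-wall boundary layer beneath a clot layer of wire-scale
#' thickness; representing them with cell-scale porosity blocks would
#' artificially narrow the lumen. This helper keeps only the wire points
#' spanning the aneurysm orifice -- those inside the sac sphere (plus a
#' margin) -- which are the segments that interact with the open flow.
#'
#' @param ws a helical `wire_set`
#' @param sac_center,sac_radius the sac sphere (m)
#' @param margin extra inclusion distance (m)
#' @return trimmed `wire_set` (wires may be split into several polylines)
#' @export
trim_wires_to_orifice <- function(ws, sac_center, sac_radius, margin = 0) {
  keep_runs <- function(w) {
    inside <- sqrt(colSums((t(w) - sac_center)^2)) <= sac_radius + margin
    r <- rle(inside)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    out <- list()
    for (i in seq_along(r$values)) {
      if (r$values[i] && r$lengths[i] >= 2L)
        out[[length(out) + 1L]] <- w[starts[i]:ends[i], , drop = FALSE]
    }
    out
  }
  wires <- do.call(c, lapply(ws$wires, keep_runs))
  if (is.null(wires) || !length(wires))
    stop("trim_wires_to_orifice: no wire points span the orifice")
  ws$wires <- wires
  ws$n_wires <- length(wires)
  ws$spheres <- .sample_spheres(wires, ws$wire_radius)
  ws
}

#' Metal coverage fraction of the deployment surface
#'
#' Total wire footprint (length x diameter) divided by the deployment
#' surface area; increases monotonically with braid angle at fixed wire
#' count and diameter. Values are clamped to 1 (crossing overlaps ignored).
#'
#' @param ws a helical `wire_set`
#' @export
device_coverage_fraction <- function(ws) {
  if (ws$type != "helical") stop("coverage fraction is defined for helical devices")
  seg <- wire_segments(ws)
  total_len <- sum(sqrt(rowSums((seg$b - seg$a)^2)))
  area <- 2 * pi * ws$surface_radius * ws$length
  min(1, total_len * 2 * ws$wire_radius / area)
}
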