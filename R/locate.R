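# Point location in a tet mesh: elements are binned by centroid on a uniform
# grid whose cell size exceeds the largest element diameter, so any point is
# contained in an element whose centroid lies in the point's cell or one of
# its 26 neighbours; candidates are then tested with barycentric coordinates.

#' Build a point locator for a mesh
#' @param mesh a `tet_mesh`
#' @param cell grid cell size (m); defaults to 2.5x the largest element size
#' @return opaque locator object for [locate_points]
#' @export
build_locator <- function(mesh, cell = NULL) {
  if (is.null(cell)) cell <- 2.5 * max(mesh$h)
  lo <- apply(mesh$nodes, 2, min) - 1e-12
  cc <- mesh$centroid
  ij <- floor(sweep(cc, 2, lo) / cell)
  dims <- apply(ij, 2, max) + 2L
  key <- ij[, 1] + dims[1] * (ij[, 2] + dims[2] * ij[, 3])
  members <- split(seq_len(nrow(cc)), key)

  t4 <- mesh$tets
  p1 <- mesh$nodes[t4[, 1], , drop = FALSE]
  a <- mesh$nodes[t4[, 2], , drop = FALSE] - p1
  b <- mesh$nodes[t4[, 3], , drop = FALSE] - p1
  c3 <- mesh$nodes[t4[, 4], , drop = FALSE] - p1
  det <- .det3(a, b, c3)
  list(cell = cell, lo = lo, dims = dims, members = members,
       p1 = p1, inv_r1 = .cross3(b, c3) / det, inv_r2 = .cross3(c3, a) / det,
       inv_r3 = .cross3(a, b) / det, tets = t4)
}

#' Locate points in the mesh
#' @param loc a [build_locator] object
#' @param p points (n x 3)
#' @param tol barycentric tolerance
#' @return list with `elem` (element index or NA) and `bary` (n x 4 matrix)
#' @export
locate_points <- function(loc, p, tol = 1e-9) {
  n <- nrow(p)
  elem <- rep(NA_integer_, n)
  bary <- matrix(NA_real_, n, 4L)
  ij <- floor(sweep(p, 2, loc$lo) / loc$cell)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (q in seq_len(n)) {
    keys <- (ij[q, 1] + off[, 1]) +
      loc$dims[1] * ((ij[q, 2] + off[, 2]) + loc$dims[2] * (ij[q, 3] + off[, 3]))
    cand <- unlist(loc$members[as.character(keys)], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    d <- p[q, ] - t(loc$p1[cand, , drop = FALSE])
    l2 <- colSums(t(loc$inv_r1[cand, , drop = FALSE]) * d)
    l3 <- colSums(t(loc$inv_r2[cand, , drop = FALSE]) * d)
    l4 <- colSums(t(loc$inv_r3[cand, , drop = FALSE]) * d)
    l1 <- 1 - l2 - l3 - l4
    ok <- which(l1 >= -tol & l2 >= -tol & l3 >= -tol & l4 >= -tol)
    if (length(ok)) {
      e <- cand[ok[1]]
      elem[q] <- e
      bary[q, ] <- c(l1[ok[1]], l2[ok[1]], l3[ok[1]], l4[ok[1]])
    }
  }
  list(elem = elem, bary = bary)
}

#' Interpolate a nodal field at located points
#' @param loc locator
#' @param located result of [locate_points]
#' @param field nodal values (n_nodes) or (n_nodes x m)
#' @return interpolated values (NA outside the mesh)
#' @export
interp_nodal <- function(loc, located, field) {
  onecol <- is.null(dim(field))
  if (onecol) field <- matrix(field, ncol = 1L)
  n <- length(located$elem)
  out <- matrix(NA_real_, n, ncol(field))
  ok <- which(!is.na(located$elem))
  for (q in ok) {
    v4 <- loc$tets[located$elem[q], ]
    out[q, ] <- located$bary[q, ] %*% field[v4, , drop = FALSE]
  }
  if (onecol) out[, 1] else out
}
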