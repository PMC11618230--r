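#' Build a tetrahedral mesh object
#'
#' Constructs the finite-volume/finite-element data attached to an
#' unstructured tetrahedral mesh: element volumes and centroids, the unique
#' triangular faces with areas, outward normals (oriented from the first
#' adjacent element `k1` towards `k2`), the centroid-to-centroid normal
#' distance across each interior face, and boundary tags.
#'
#' Element orientation is fixed automatically (node reordering) so that all
#' signed volumes are positive.
#'
#' @param nodes numeric matrix (n_nodes x 3) of coordinates (m)
#' @param tets integer matrix (n_elem x 4) of node indices
#' @param classify_boundary function(face_centroids, face_normals) returning
#'   an integer tag per boundary face: 1 inlet, 2 outlet, 3 wall. If NULL all
#'   boundary faces are walls.
#' @param geom optional list of analytic geometry metadata (kept verbatim)
#' @return object of class `tet_mesh`: a list with `nodes`, `tets`, `V`,
#'   `centroid`, `h`, face tables (`face_nodes`, `face_area`, `face_normal`,
#'   `face_k1`, `face_k2`, `face_ds`, `face_tag`, `face_centroid`),
#'   per-element face incidence (`elem_face`, `elem_face_sign`), node tags
#'   (`node_tag`) and `geom`.
#' @export
build_tet_mesh <- function(nodes, tets, classify_boundary = NULL, geom = list()) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L || ncol(tets) != 4L) stop("nodes must be n x 3, tets n x 4")
  ne <- nrow(tets)
  if (ne == 0L) stop("empty mesh")

  p1 <- nodes[tets[, 1L], , drop = FALSE]
  p2 <- nodes[tets[, 2L], , drop = FALSE]
  p3 <- nodes[tets[, 3L], , drop = FALSE]
  p4 <- nodes[tets[, 4L], , drop = FALSE]
  v6 <- .det3(p2 - p1, p3 - p1, p4 - p1)
  flip <- v6 < 0
  if (any(flip)) {   # swap nodes 3,4 to make orientation positive
    tmp <- tets[flip, 3L]; tets[flip, 3L] <- tets[flip, 4L]; tets[flip, 4L] <- tmp
    p3 <- nodes[tets[, 3L], , drop = FALSE]
    p4 <- nodes[tets[, 4L], , drop = FALSE]
    v6 <- .det3(p2 - p1, p3 - p1, p4 - p1)
  }
  V <- v6 / 6
  if (any(V <= 0)) stop("degenerate element(s) with non-positive volume")
  centroid <- (p1 + p2 + p3 + p4) / 4

  # four faces per element, each opposite one vertex
  fi <- rbind(tets[, c(2L, 3L, 4L)],
              tets[, c(1L, 4L, 3L)],
              tets[, c(1L, 2L, 4L)],
              tets[, c(1L, 3L, 2L)])
  owner <- rep.int(seq_len(ne), 4L)
  key <- .face_key(fi)
  ord <- order(key)
  key_s <- key[ord]
  first <- !duplicated(key_s)
  fid_s <- cumsum(first)
  fid <- integer(length(key)); fid[ord] <- fid_s
  nf <- fid_s[length(fid_s)]

  face_nodes <- matrix(0L, nf, 3L)
  face_k1 <- integer(nf); face_k2 <- rep(NA_integer_, nf)
  seen <- logical(nf)
  # first occurrence defines face orientation (outward for its owner element)
  idx_first <- ord[first]
  face_nodes[, ] <- fi[idx_first, ]
  face_k1 <- owner[idx_first]
  idx_second <- ord[!first]
  if (length(idx_second)) {
    f2 <- fid[idx_second]
    if (anyDuplicated(f2)) stop("non-manifold mesh: face shared by > 2 elements")
    face_k2[f2] <- owner[idx_second]
  }

  a <- nodes[face_nodes[, 1L], , drop = FALSE]
  b <- nodes[face_nodes[, 2L], , drop = FALSE]
  c3 <- nodes[face_nodes[, 3L], , drop = FALSE]
  av <- .cross3(b - a, c3 - a) / 2          # area vector, outward w.r.t. k1
  face_area <- sqrt(rowSums(av^2))
  if (any(face_area <= 0)) stop("degenerate face")
  face_normal <- av / face_area
  face_centroid <- (a + b + c3) / 3

  # verify orientation: normal must point away from k1's centroid
  d1 <- rowSums((face_centroid - centroid[face_k1, , drop = FALSE]) * face_normal)
  if (any(d1 <= 0)) stop("internal error: face orientation inconsistent")

  interior <- !is.na(face_k2)
  face_ds <- numeric(nf)
  face_ds[interior] <- abs(rowSums(
    (centroid[face_k2[interior], , drop = FALSE] -
     centroid[face_k1[interior], , drop = FALSE]) *
      face_normal[interior, , drop = FALSE]))
  # boundary: centroid-to-face normal distance (used for one-sided gradients)
  face_ds[!interior] <- abs(rowSums(
    (face_centroid[!interior, , drop = FALSE] -
     centroid[face_k1[!interior], , drop = FALSE]) *
      face_normal[!interior, , drop = FALSE]))
  if (any(face_ds <= 0)) stop("zero centroid distance across a face")

  face_tag <- integer(nf)  # 0 interior
  bidx <- which(!interior)
  if (length(bidx)) {
    if (is.null(classify_boundary)) {
      face_tag[bidx] <- 3L
    } else {
      tg <- classify_boundary(face_centroid[bidx, , drop = FALSE],
                              face_normal[bidx, , drop = FALSE])
      if (length(tg) != length(bidx) || !all(tg %in% 1:3))
        stop("classify_boundary must return tags in {1,2,3} per boundary face")
      face_tag[bidx] <- as.integer(tg)
    }
  }

  # element -> face incidence; sign +1 where the stored normal is outward
  # for this element (i.e. the element is k1 of the face)
  elem_face <- matrix(0L, ne, 4L)
  elem_face_sign <- matrix(0, ne, 4L)
  for (loc in 1:4) {
    rows <- (loc - 1L) * ne + seq_len(ne)
    elem_face[, loc] <- fid[rows]
    elem_face_sign[, loc] <- ifelse(face_k1[fid[rows]] == seq_len(ne), 1, -1)
  }

  # node tags from boundary faces (priority: wall > inlet > outlet)
  nn <- nrow(nodes)
  node_tag <- integer(nn)
  for (tg in c(2L, 1L, 3L)) {
    f <- which(face_tag == tg)
    if (length(f)) node_tag[unique(as.vector(face_nodes[f, ]))] <- tg
  }

  m <- list(nodes = nodes, tets = tets, V = V, centroid = centroid,
            h = V^(1 / 3),
            face_nodes = face_nodes, face_area = face_area,
            face_normal = face_normal, face_centroid = face_centroid,
            face_k1 = face_k1, face_k2 = face_k2, face_ds = face_ds,
            face_tag = face_tag,
            elem_face = elem_face, elem_face_sign = elem_face_sign,
            node_tag = node_tag, geom = geom,
            classify_boundary = classify_boundary)
  class(m) <- "tet_mesh"
  m
}

.det3 <- function(u, v, w) {
  u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
  u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
  u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
}

.cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

.face_key <- function(f) {
  # vectorized 3-element sort (min/mid/max network)
  a <- f[, 1L]; b <- f[, 2L]; c3 <- f[, 3L]
  lo <- pmin.int(a, b); hi <- pmax.int(a, b)
  mid <- pmin.int(hi, c3); hi <- pmax.int(hi, c3)
  lo2 <- pmin.int(lo, mid); mid <- pmax.int(lo, mid)
  paste(lo2, mid, hi, sep = "_")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "elements,",
      length(x$face_area), "faces\n")
  cat("  volume:", format(sum(x$V), digits = 6), "m^3;  h in [",
      format(min(x$h), digits = 3), ",", format(max(x$h), digits = 3), "] m\n")
  nb <- table(factor(x$face_tag, levels = 0:3,
                     labels = c("interior", "inlet", "outlet", "wall")))
  cat("  faces:", paste(names(nb), nb, collapse = ", "), "\n")
  invisible(x)
}

#' Total mesh volume (m^3)
#' @param mesh a [build_tet_mesh] object
#' @export
mesh_volume <- function(mesh) sum(mesh$V)

#' Summed area of boundary faces with a given tag
#' @param mesh a `tet_mesh`
#' @param tag one of "inlet", "outlet", "wall"
#' @export
boundary_area <- function(mesh, tag = c("inlet", "outlet", "wall")) {
  tag <- match.arg(tag)
  code <- match(tag, c("inlet", "outlet", "wall"))
  sum(mesh$face_area[mesh$face_tag == code])
}

#' Per-element face-closure defect
#'
#' For every element the outward area vectors of its four faces must sum to
#' zero. Returns the maximum norm of the defect relative to the element's
#' total face area; a healthy mesh gives ~1e-14.
#'
#' @param mesh a `tet_mesh`
#' @export
mesh_closure_defect <- function(mesh) {
  ne <- nrow(mesh$tets)
  defect <- matrix(0, ne, 3L)
  tot <- numeric(ne)
  for (loc in 1:4) {
    f <- mesh$elem_face[, loc]
    s <- mesh$elem_face_sign[, loc]
    defect <- defect + s * mesh$face_area[f] * mesh$face_normal[f, , drop = FALSE]
    tot <- tot + mesh$face_area[f]
  }
  max(sqrt(rowSums(defect^2)) / tot)
}

#' Unique edges of a tetrahedral mesh
#' @param mesh a `tet_mesh`
#' @return integer matrix (n_edges x 2), each row an ascending node pair
#' @export
mesh_edges <- function(mesh) {
  t4 <- mesh$tets
  e <- rbind(t4[, c(1, 2)], t4[, c(1, 3)], t4[, c(1, 4)],
             t4[, c(2, 3)], t4[, c(2, 4)], t4[, c(3, 4)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}
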