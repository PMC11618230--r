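#' Distance from points to the nearest wire centerline
#'
#' Exact point-to-segment distance over all wire polyline segments, with a
#' uniform-grid prefilter so only points within `cutoff` of a segment are
#' tested exactly; points farther than `cutoff` from every segment receive
#' the value `cutoff`. Use `cutoff = Inf` for exact distances everywhere
#' (quadratic cost; fine on small meshes and used as the test oracle path).
#'
#' @param p points (n x 3)
#' @param ws a `wire_set`
#' @param cutoff truncation distance (m) or Inf
#' @return numeric vector of centerline distances (m); `Inf` if the wire set
#'   is empty
#' @export
dist_to_wires <- function(p, ws, cutoff = Inf) {
  n <- nrow(p)
  if (is.null(ws) || length(ws$wires) == 0L) return(rep(Inf, n))
  seg <- wire_segments(ws)
  d <- rep(if (is.infinite(cutoff)) Inf else cutoff, n)
  ab <- seg$b - seg$a
  L2 <- rowSums(ab^2)
  ns <- nrow(seg$a)

  if (is.infinite(cutoff)) {
    for (j in seq_len(ns)) {
      d <- pmin(d, .pt_seg_dist(p, seg$a[j, ], ab[j, ], L2[j]))
    }
    return(d)
  }

  # bin points on a uniform grid; visit only cells overlapping each segment's
  # cutoff-expanded bounding box
  cell <- max(cutoff, sqrt(max(L2)) / 2)
  lo <- apply(p, 2, min) - 1e-12
  ij <- floor(sweep(p, 2, lo) / cell)
  dims <- apply(ij, 2, max) + 1L
  keyv <- ij[, 1] + dims[1] * (ij[, 2] + dims[2] * ij[, 3])
  buckets <- split(seq_len(n), keyv)
  for (j in seq_len(ns)) {
    blo <- floor((pmin(seg$a[j, ], seg$b[j, ]) - cutoff - lo) / cell)
    bhi <- floor((pmax(seg$a[j, ], seg$b[j, ]) + cutoff - lo) / cell)
    blo <- pmax(blo, 0); bhi <- pmin(bhi, dims - 1L)
    if (any(bhi < blo)) next
    cells <- as.matrix(expand.grid(blo[1]:bhi[1], blo[2]:bhi[2], blo[3]:bhi[3]))
    keys <- as.character(cells[, 1] + dims[1] * (cells[, 2] + dims[2] * cells[, 3]))
    idx <- unlist(buckets[keys], use.names = FALSE)
    if (is.null(idx) || !length(idx)) next
    d[idx] <- pmin(d[idx], .pt_seg_dist(p[idx, , drop = FALSE],
                                        seg$a[j, ], ab[j, ], L2[j]))
  }
  d
}

.pt_seg_dist <- function(p, a, ab, L2) {
  pa1 <- p[, 1] - a[1]; pa2 <- p[, 2] - a[2]; pa3 <- p[, 3] - a[3]
  if (L2 <= .Machine$double.eps) {
    return(sqrt(pa1^2 + pa2^2 + pa3^2))
  }
  t <- (pa1 * ab[1] + pa2 * ab[2] + pa3 * ab[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pa1 - t * ab[1])^2 + (pa2 - t * ab[2])^2 + (pa3 - t * ab[3])^2)
}

#' Immersed-boundary representation of a deployed device
#'
#' Computes (a) the per-element distance field `r_field`: distance from each
#' element centroid to the nearest wire *surface* (centerline distance minus
#' wire radius, floored at 0); (b) the mesh edges cut by the wire spheres
#' (one endpoint inside the wire, the other outside); and (c) the `ib_nodes`
#' where no-slip is imposed: every node inside a wire plus, for each cut
#' edge, the endpoint nearest the wire.
#'
#' An empty wire set yields no cut edges and `r_field = Inf`.
#'
#' @param mesh a `tet_mesh`
#' @param wires a `wire_set` or NULL
#' @param cutoff distance-field truncation (m); defaults to 40 wire radii
#'   plus twice the largest element size, far beyond the reach of the
#'   proximity switch
#' @return object of class `immersed_boundary` with `r_field`, `node_dist`
#'   (nodal distance to wire surface), `cut_edges`, `ib_nodes`, `cutoff`
#' @export
compute_immersed_boundary <- function(mesh, wires, cutoff = NULL) {
  ne <- nrow(mesh$tets)
  if (is.null(wires) || length(wires$wires) == 0L) {
    out <- list(r_field = rep(Inf, ne),
                node_dist = rep(Inf, nrow(mesh$nodes)),
                cut_edges = matrix(0L, 0L, 2L), ib_nodes = integer(0),
                cutoff = Inf)
    class(out) <- "immersed_boundary"
    return(out)
  }
  wr <- wires$wire_radius
  if (is.null(cutoff)) cutoff <- 40 * wr + 2 * max(mesh$h)
  dc_elem <- dist_to_wires(mesh$centroid, wires, cutoff)
  dc_node <- dist_to_wires(mesh$nodes, wires, cutoff)
  r_field <- pmax(dc_elem - wr, 0)
  node_dist <- dc_node - wr        # signed: negative inside a wire

  edges <- mesh_edges(mesh)
  d1 <- node_dist[edges[, 1]]
  d2 <- node_dist[edges[, 2]]
  cut <- (d1 < 0) != (d2 < 0)
  cut_edges <- edges[cut, , drop = FALSE]
  inside <- which(node_dist < 0)
  nearer <- ifelse(abs(d1[cut]) <= abs(d2[cut]), cut_edges[, 1], cut_edges[, 2])
  ib_nodes <- sort(unique(c(inside, nearer)))

  out <- list(r_field = r_field, node_dist = node_dist,
              cut_edges = cut_edges, ib_nodes = ib_nodes, cutoff = cutoff)
  class(out) <- "immersed_boundary"
  out
}

#' @export
print.immersed_boundary <- function(x, ...) {
  cat("immersed_boundary:", length(x$ib_nodes), "no-slip nodes,",
      nrow(x$cut_edges), "cut edges\n")
  invisible(x)
}
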