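# Local mesh refinement by longest-edge (Rivara) bisection.
#
# A bisection splits a tet at the midpoint of one edge into two equal-volume
# children. To keep the mesh conforming, an edge is only split when it is the
# longest edge of every element sharing it; otherwise refinement propagates
# to the offending neighbours first (longest-edge propagation path). The
# propagation terminates because edge lengths strictly decrease along it.

#' Refine the mesh around immersed wires
#'
#' Elements containing wire-cut edges are bisected until their volume drops
#' to 1/8 of the pre-refinement value per level (three bisections), halving
#' the local element size h = V^(1/3) per level. Conformity is maintained by
#' longest-edge propagation, so some neighbouring elements are refined too.
#'
#' @param mesh a `tet_mesh`
#' @param ib an `immersed_boundary` for `mesh`
#' @param levels number of halvings of the local element size (>= 0)
#' @param wires the `wire_set`; required when `levels > 1` so cut edges can
#'   be re-detected on the intermediate meshes
#' @return refined `tet_mesh`
#' @export
refine_near_wires <- function(mesh, ib, levels, wires = NULL) {
  if (levels < 0) stop("levels must be >= 0")
  if (levels == 0) return(mesh)
  if (levels > 1 && is.null(wires))
    stop("wires must be supplied for levels > 1")
  for (lev in seq_len(levels)) {
    if (lev > 1) ib <- compute_immersed_boundary(mesh, wires)
    marked <- .elems_with_cut_edges(mesh, ib)
    if (!any(marked)) break
    for (sweep in 1:3) {
      res <- .bisect_marked(mesh$nodes, mesh$tets, marked)
      mesh0 <- mesh
      mesh <- build_tet_mesh(res$nodes, res$tets, mesh0$classify_boundary,
                             geom = mesh0$geom)
      marked <- res$marked
      if (length(marked) != nrow(mesh$tets)) stop("internal: marker mismatch")
    }
  }
  mesh
}

.elems_with_cut_edges <- function(mesh, ib) {
  ne <- nrow(mesh$tets)
  if (nrow(ib$cut_edges) == 0L) return(logical(ne))
  cutkey <- paste(ib$cut_edges[, 1], ib$cut_edges[, 2], sep = "_")
  t4 <- mesh$tets
  marked <- logical(ne)
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (pr in pairs) {
    a <- pmin.int(t4[, pr[1]], t4[, pr[2]])
    b <- pmax.int(t4[, pr[1]], t4[, pr[2]])
    marked <- marked | (paste(a, b, sep = "_") %in% cutkey)
  }
  marked
}

# One sweep: bisect every marked tet once (plus conformity propagation).
# Children of marked tets are marked; conformity-driven bisections of
# unmarked tets leave unmarked children.
.bisect_marked <- function(nodes, tets, marked) {
  # mutable state shared by the helpers below (environment = by-reference)
  st <- new.env(parent = emptyenv())
  nmax <- 8L * nrow(tets) + 64L
  st$nodes <- rbind(nodes, matrix(0, nrow(nodes), 3L))
  st$nn <- nrow(nodes)
  st$tets <- rbind(tets, matrix(0L, nmax, 4L))
  st$alive <- c(rep(TRUE, nrow(tets)), logical(nmax))
  st$marked <- c(marked, logical(nmax))
  st$pending <- c(marked, logical(nmax))  # needs one bisection this sweep
  st$nt <- nrow(tets)
  st$edge_tets <- new.env(parent = emptyenv())  # edge key -> tet ids
  st$mid <- new.env(parent = emptyenv())        # edge key -> midpoint node id
  for (t in seq_len(st$nt)) .register_edges(st, t)

  for (t0 in which(marked)) {
    if (!st$pending[t0] || !st$alive[t0]) next
    stack <- t0
    guard <- 0L
    while (length(stack)) {
      guard <- guard + 1L
      if (guard > 200000L) stop("refinement propagation failed to terminate")
      t <- stack[length(stack)]
      if (!st$alive[t]) { stack <- stack[-length(stack)]; next }
      e <- .longest_edge(st, t)
      sharers <- .edge_sharers(st, e$key)
      # neighbours for which e is not the longest edge must be split first
      worse <- integer(0)
      for (s in sharers) {
        es <- .longest_edge(st, s)
        if (es$key != e$key) worse <- c(worse, s)
      }
      if (length(worse)) {
        stack <- c(stack, worse[1L])
      } else {
        .bisect_edge(st, e, sharers)
        stack <- stack[-length(stack)]
      }
    }
  }
  keep <- which(st$alive[seq_len(st$nt)])
  list(nodes = st$nodes[seq_len(st$nn), , drop = FALSE],
       tets = st$tets[keep, , drop = FALSE],
       marked = st$marked[keep])
}

.ekey <- function(a, b) paste(min(a, b), max(a, b), sep = "_")

.register_edges <- function(st, t) {
  v <- st$tets[t, ]
  for (pr in list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))) {
    k <- .ekey(v[pr[1]], v[pr[2]])
    st$edge_tets[[k]] <- c(st$edge_tets[[k]], t)
  }
}

.edge_sharers <- function(st, key) {
  ids <- st$edge_tets[[key]]
  ids[st$alive[ids]]
}

.longest_edge <- function(st, t) {
  v <- st$tets[t, ]
  best_len <- -1; best <- NULL
  for (pr in list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))) {
    a <- v[pr[1]]; b <- v[pr[2]]
    len <- sum((st$nodes[a, ] - st$nodes[b, ])^2)
    k <- .ekey(a, b)
    # exact-tie edges are broken deterministically on the edge key so that
    # all elements sharing an edge agree on their longest edges
    if (len > best_len || (len == best_len && k < best$key)) {
      best_len <- len
      best <- list(a = min(a, b), b = max(a, b), key = k)
    }
  }
  best
}

.bisect_edge <- function(st, e, sharers) {
  m <- st$mid[[e$key]]
  if (is.null(m)) {
    st$nn <- st$nn + 1L
    if (st$nn > nrow(st$nodes))
      st$nodes <- rbind(st$nodes, matrix(0, nrow(st$nodes), 3L))
    st$nodes[st$nn, ] <- (st$nodes[e$a, ] + st$nodes[e$b, ]) / 2
    m <- st$nn
    st$mid[[e$key]] <- m
  }
  for (t in sharers) {
    v <- st$tets[t, ]
    st$alive[t] <- FALSE
    for (child_repl in c(e$a, e$b)) {
      w <- v
      w[w == child_repl] <- m
      st$nt <- st$nt + 1L
      if (st$nt > nrow(st$tets)) {
        st$tets <- rbind(st$tets, matrix(0L, nrow(st$tets), 4L))
        n_extra <- nrow(st$tets) - length(st$alive)
        st$alive <- c(st$alive, logical(n_extra))
        st$marked <- c(st$marked, logical(n_extra))
        st$pending <- c(st$pending, logical(n_extra))
      }
      st$tets[st$nt, ] <- w
      st$alive[st$nt] <- TRUE
      st$marked[st$nt] <- st$marked[t]
      st$pending[st$nt] <- FALSE
      .register_edges(st, st$nt)
    }
    st$pending[t] <- FALSE
  }
}
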