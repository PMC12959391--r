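# Geodesic distances on the skin: Dijkstra shortest paths on the mesh edge
# graph augmented with one midpoint node per edge (and the in-face
# midpoint-midpoint / midpoint-opposite-vertex links). This over-estimates the
# exact polyhedral geodesic by a bounded, refinement-controlled amount and is
# exactly checkable against an independent graph shortest-path oracle.

#' Build the subdivided geodesic graph of a mesh
#'
#' Nodes are the mesh vertices plus one midpoint per unique edge; links are
#' the two halves of each edge, the three midpoint-midpoint links of each
#' face, and each midpoint to the opposite corner. Weights are rest-frame
#' Euclidean lengths.
#'
#' @param mesh A `skinned_mesh`.
#' @return A list of class `geodesic_graph`: `g` (igraph), `node_pos`,
#'   `node_comp` (each node as a convex combination of up to 2 mesh
#'   vertices), `n_vertices`, and `edge_mid` (edge-key to node id lookup).
#' @export
build_geodesic_graph <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  nV <- nrow(V)
  e_all <- mesh_edges(F)
  key_all <- e_all[, 1] * (nV + 1) + e_all[, 2]
  uk <- !duplicated(key_all)
  E <- e_all[uk, , drop = FALSE]
  nE <- nrow(E)
  mid_id <- nV + seq_len(nE)
  edge_mid <- stats::setNames(mid_id, key_all[uk])
  mid_pos <- (V[E[, 1], ] + V[E[, 2], ]) / 2
  node_pos <- rbind(V, mid_pos)
  node_comp <- rbind(
    cbind(seq_len(nV), seq_len(nV), 1, 0),
    cbind(E[, 1], E[, 2], 0.5, 0.5)
  )
  ekey <- function(a, b) pmin(a, b) * (nV + 1) + pmax(a, b)
  m_ab <- edge_mid[as.character(ekey(F[, 1], F[, 2]))]
  m_bc <- edge_mid[as.character(ekey(F[, 2], F[, 3]))]
  m_ca <- edge_mid[as.character(ekey(F[, 3], F[, 1]))]
  links <- rbind(
    cbind(E[, 1], mid_id), cbind(mid_id, E[, 2]),   # split edges
    cbind(m_ab, m_bc), cbind(m_bc, m_ca), cbind(m_ca, m_ab),
    cbind(m_ab, F[, 3]), cbind(m_bc, F[, 1]), cbind(m_ca, F[, 2])
  )
  lkey <- pmin(links[, 1], links[, 2]) * 1e7 + pmax(links[, 1], links[, 2])
  keep <- !duplicated(lkey)
  links <- links[keep, , drop = FALSE]
  w <- sqrt(rowSums((node_pos[links[, 1], ] - node_pos[links[, 2], ])^2))
  g <- igraph::make_empty_graph(n = nrow(node_pos), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(links)))
  igraph::E(g)$weight <- w
  structure(list(g = g, node_pos = node_pos, node_comp = node_comp,
                 n_vertices = nV, edge_mid = edge_mid, links = links,
                 weights = w),
            class = "geodesic_graph")
}

# Map a surface point onto the graph: an existing node when it coincides with
# a face corner or edge midpoint, otherwise a temporary node wired to the
# face's three corners and three midpoints.
sp_graph_node <- function(mesh, geo, sp, tol = 1e-6) {
  b <- sp$bary
  ids <- mesh$faces[sp$face, ]
  corner <- which(b > 1 - tol)
  if (length(corner) == 1) return(list(node = ids[corner], temp = FALSE))
  zero <- which(b < tol)
  if (length(zero) == 1) {
    pair <- ids[-zero]
    if (abs(b[-zero][1] - 0.5) < tol) {
      nV <- geo$n_vertices
      key <- as.character(min(pair) * (nV + 1) + max(pair))
      return(list(node = unname(geo$edge_mid[key]), temp = FALSE))
    }
  }
  list(node = NA, temp = TRUE)
}

face_nodes <- function(geo, mesh, face) {
  ids <- mesh$faces[face, ]
  nV <- geo$n_vertices
  ek <- function(a, b) as.character(min(a, b) * (nV + 1) + max(a, b))
  mids <- c(geo$edge_mid[ek(ids[1], ids[2])],
            geo$edge_mid[ek(ids[2], ids[3])],
            geo$edge_mid[ek(ids[3], ids[1])])
  c(ids, unname(mids))
}

#' Geodesic distance between two surface points
#'
#' Shortest-path length over the subdivided edge graph, with the two surface
#' points inserted as temporary barycentric nodes wired to their faces'
#' corners and edge midpoints. Symmetric; returns the polyline path as an
#' attribute.
#'
#' @param mesh A `skinned_mesh`.
#' @param a,b `surface_point`s.
#' @param geo Optional precomputed [build_geodesic_graph()] result.
#' @return Length in meters, with attributes `path` (K x 3 polyline) and
#'   `nodes` (graph node ids, `NA` for the temporary endpoints).
#' @export
geodesic_distance <- function(mesh, a, b, geo = NULL) {
  if (is.null(geo)) geo <- build_geodesic_graph(mesh)
  pa <- surface_point_position(mesh, a)
  pb <- surface_point_position(mesh, b)
  if (a$face == b$face && max(abs(a$bary - b$bary)) < 1e-12) {
    out <- 0
    attr(out, "path") <- rbind(pa, pb)
    attr(out, "nodes") <- rep(NA_integer_, 2)
    return(out)
  }
  na <- sp_graph_node(mesh, geo, a)
  nb <- sp_graph_node(mesh, geo, b)
  g <- geo$g
  pos <- geo$node_pos
  nodes_extra <- 0L
  attach_temp <- function(g, face, p) {
    fn <- face_nodes(geo, mesh, face)
    g <- igraph::add_vertices(g, 1)
    id <- igraph::vcount(g)
    w <- sqrt(rowSums(sweep(pos[fn, , drop = FALSE], 2, p)^2))
    g <- igraph::add_edges(g, as.vector(rbind(rep(id, length(fn)), fn)),
                           weight = w)
    list(g = g, id = id)
  }
  if (na$temp) {
    tmp <- attach_temp(g, a$face, pa); g <- tmp$g; na$node <- tmp$id
    nodes_extra <- nodes_extra + 1L
  }
  if (nb$temp) {
    tmp <- attach_temp(g, b$face, pb); g <- tmp$g; nb$node <- tmp$id
    nodes_extra <- nodes_extra + 1L
  }
  if (na$node == nb$node) {
    d <- sqrt(sum((pa - pb)^2))
    out <- d
    attr(out, "path") <- rbind(pa, pb)
    attr(out, "nodes") <- rep(NA_integer_, 2)
    return(out)
  }
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = na$node, to = nb$node,
                           weights = igraph::E(g)$weight,
                           output = "both"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) == 0) stop("no geodesic path: mesh is disconnected between the two points",
                            call. = FALSE)
  d <- sum(igraph::E(g)$weight[as.integer(sp$epath[[1]])])
  coords <- matrix(0, length(vp), 3)
  node_ids <- vp
  for (i in seq_along(vp)) {
    if (vp[i] <= nrow(pos)) {
      coords[i, ] <- pos[vp[i], ]
    } else {
      coords[i, ] <- if (na$temp && vp[i] == na$node) pa else pb
      node_ids[i] <- NA_integer_
    }
  }
  out <- d
  attr(out, "path") <- coords
  attr(out, "nodes") <- node_ids
  out
}

# Single-source distances from a graph node to all nodes.
geo_dists_from_node <- function(geo, node) {
  as.vector(igraph::distances(geo$g, v = node, weights = geo$weights))
}

# --- batched posed path lengths --------------------------------------------
#
# A surface path is a chain of graph nodes; each node is a fixed convex
# combination of mesh vertices (a material point on the skin). Posing the
# body moves those material points by linear blend skinning; the path length
# under a pose is the posed polyline length. This is evaluated for many
# paths and many frames at once via one dense matrix product per coordinate:
# posed positions P_c = B %*% S_c, with B the (points x 4J) skinning basis
# and S_c the (4J x frames) stacked joint transforms.

# Build the fixed skinning basis for a set of path points.
# pts: list(pos = K x 3, w = K x J weight rows)
path_basis <- function(pts, skeleton) {
  K <- nrow(pts$pos)
  J <- ncol(pts$w)
  B <- matrix(0, K, 4L * J)
  for (j in seq_len(J)) {
    cols <- (j - 1L) * 4L + 1:4
    rel <- sweep(pts$pos, 2, skeleton$rest_pos[j, ])
    B[, cols] <- cbind(pts$w[, j] * rel, pts$w[, j])
  }
  B
}

# Posed positions of path points for an angle matrix (frames x 39).
# Returns list(x, y, z), each K x T.
posed_point_coords <- function(B, skeleton, angles) {
  fk <- fk_batch(skeleton, angles)
  nT <- nrow(as.matrix(angles))
  J <- length(skeleton$joints)
  S <- lapply(1:3, function(c) matrix(0, 4L * J, nT))
  for (j in seq_len(J)) {
    R <- fk$R[[j]]; P <- fk$P[[j]]
    rows <- (j - 1L) * 4L + 1:4
    for (c in 1:3) {
      # row k of M_j = (R[, c-th row elements]); M_j is R^T stacked over t
      S[[c]][rows, ] <- t(cbind(R[, c], R[, 3 + c], R[, 6 + c], P[, c]))
    }
  }
  list(x = B %*% S[[1]], y = B %*% S[[2]], z = B %*% S[[3]])
}

# Lengths of several paths over many frames.
# paths: list of integer index vectors into the point set used to build B.
# Returns T x n_paths matrix.
path_lengths_batch <- function(B, skeleton, angles, paths, chunk = 4000L) {
  angles <- as.matrix(angles)
  nT <- nrow(angles)
  from <- unlist(lapply(paths, function(p) p[-length(p)]))
  to <- unlist(lapply(paths, function(p) p[-1]))
  grp <- rep(seq_along(paths), vapply(paths, length, 1L) - 1L)
  out <- matrix(0, nT, length(paths))
  for (s in seq(1L, nT, by = chunk)) {
    e <- min(nT, s + chunk - 1L)
    pc <- posed_point_coords(B, skeleton, angles[s:e, , drop = FALSE])
    seg <- sqrt((pc$x[to, , drop = FALSE] - pc$x[from, , drop = FALSE])^2 +
                (pc$y[to, , drop = FALSE] - pc$y[from, , drop = FALSE])^2 +
                (pc$z[to, , drop = FALSE] - pc$z[from, , drop = FALSE])^2)
    out[s:e, ] <- t(rowsum(seg, grp))
  }
  out
}

# Collect unique graph nodes of a set of node paths into a point set.
# Returns list(pts = list(pos, w), paths = reindexed paths).
collect_path_points <- function(geo, mesh, node_paths) {
  all_nodes <- sort(unique(unlist(node_paths)))
  comp <- geo$node_comp[all_nodes, , drop = FALSE]
  pos <- geo$node_pos[all_nodes, , drop = FALSE]
  W <- mesh$weights[comp[, 1], , drop = FALSE] * comp[, 3] +
    mesh$weights[comp[, 2], , drop = FALSE] * comp[, 4]
  lookup <- integer(max(all_nodes))
  lookup[all_nodes] <- seq_along(all_nodes)
  list(pts = list(pos = pos, w = W),
       paths = lapply(node_paths, function(p) lookup[p]))
}
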