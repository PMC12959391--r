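# Procedural skin mesh: one generalized-cylinder ("tube") per body chain,
# closed with cap fans, with each limb's proximal cap apex welded onto the
# nearest torso vertex so the skin is a single connected, edge-manifold
# surface that geodesics can cross at the joints.

# Perpendicular frames along a polyline by parallel transport.
transport_frames <- function(centers) {
  n <- nrow(centers)
  tangents <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- max(1L, i - 1L); b <- min(n, i + 1L)
    t <- centers[b, ] - centers[a, ]
    tangents[i, ] <- t / sqrt(sum(t^2))
  }
  e1 <- matrix(0, n, 3); e2 <- matrix(0, n, 3)
  t0 <- tangents[1, ]
  ref <- if (abs(t0[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  u <- ref - sum(ref * t0) * t0
  u <- u / sqrt(sum(u^2))
  e1[1, ] <- u
  e2[1, ] <- c(t0[2] * u[3] - t0[3] * u[2],
               t0[3] * u[1] - t0[1] * u[3],
               t0[1] * u[2] - t0[2] * u[1])
  for (i in 2:n) {
    u <- e1[i - 1L, ]
    t <- tangents[i, ]
    u <- u - sum(u * t) * t
    u <- u / sqrt(sum(u^2))
    e1[i, ] <- u
    e2[i, ] <- c(t[2] * u[3] - t[3] * u[2],
                 t[3] * u[1] - t[1] * u[3],
                 t[1] * u[2] - t[2] * u[1])
  }
  list(t = tangents, e1 = e1, e2 = e2)
}

# Resample a polyline (with per-point radii) at roughly uniform arc spacing.
resample_polyline <- function(pts, radii, ds) {
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  n <- max(3L, ceiling(total / ds) + 1L)
  si <- seq(0, total, length.out = n)
  out <- sapply(1:3, function(k) stats::approx(s, pts[, k], xout = si)$y)
  r <- stats::approx(s, radii, xout = si)$y
  list(centers = out, radii = r)
}

# Build one closed tube. cap_start/cap_end: "apex" grows a cap vertex,
# an integer welds the fan onto that existing vertex id.
add_tube <- function(acc, centerline, radii, res, ds, cap_start = "apex",
                     cap_end = "apex") {
  rs <- resample_polyline(centerline, radii, ds)
  centers <- rs$centers; rr <- rs$radii
  n <- nrow(centers)
  fr <- transport_frames(centers)
  ang <- (0:(res - 1L)) * 2 * pi / res
  base <- nrow(acc$vertices)
  verts <- matrix(0, n * res, 3)
  for (i in seq_len(n)) {
    ring <- centers[rep(i, res), ] +
      rr[i] * (cos(ang) %o% fr$e1[i, ] + sin(ang) %o% fr$e2[i, ])
    verts[(i - 1L) * res + 1:res, ] <- ring
  }
  acc$vertices <- rbind(acc$vertices, verts)
  ring_id <- function(i) base + (i - 1L) * res + 1:res
  faces <- vector("list", 0)
  for (i in seq_len(n - 1L)) {
    a <- ring_id(i); b <- ring_id(i + 1L)
    nx <- c(2:res, 1L)
    faces[[length(faces) + 1L]] <- cbind(a, b, b[nx])
    faces[[length(faces) + 1L]] <- cbind(a, b[nx], a[nx])
  }
  cap <- function(ring, end_center, tangent, r, existing) {
    if (identical(existing, "apex")) {
      apex <- end_center + tangent * (0.75 * r)
      acc$vertices <<- rbind(acc$vertices, matrix(apex, 1, 3))
      aid <- nrow(acc$vertices)
    } else {
      aid <- existing
    }
    nx <- c(2:res, 1L)
    faces[[length(faces) + 1L]] <<- cbind(ring, ring[nx], rep(aid, res))
    aid
  }
  a0 <- cap(ring_id(1L), centers[1, ], -fr$t[1, ], rr[1], cap_start)
  a1 <- cap(ring_id(n), centers[n, ], fr$t[n, ], rr[n], cap_end)
  acc$faces <- rbind(acc$faces, do.call(rbind, faces))
  acc$cap_ids <- c(acc$cap_ids, a0, a1)
  acc
}

nearest_vertex <- function(vertices, point) {
  d2 <- (vertices[, 1] - point[1])^2 + (vertices[, 2] - point[2])^2 +
    (vertices[, 3] - point[3])^2
  which.min(d2)
}

point_segment_dist <- function(pts, a, b) {
  ab <- b - a
  ab2 <- sum(ab^2)
  if (ab2 < 1e-12) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2 + (pts[, 3] - a[3])^2))
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
          (pts[, 3] - a[3]) * ab[3]) / ab2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]; pz <- a[3] + t * ab[3]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2 + (pts[, 3] - pz)^2)
}

# Smooth distance-based skinning weights: Gaussian falloff of the distance to
# each joint's bone segments, pruned below 1e-3 of the per-vertex maximum and
# renormalized to row sums of exactly 1.
skin_weights <- function(vertices, skeleton, blend_radius) {
  nj <- length(skeleton$joints)
  W <- matrix(0, nrow(vertices), nj)
  for (j in seq_len(nj)) {
    segs <- skeleton$bones[[j]]
    if (length(segs) == 0) {
      d <- sqrt(rowSums(sweep(vertices, 2, skeleton$rest_pos[j, ])^2))
    } else {
      d <- Reduce(pmin, lapply(segs, function(tip) {
        point_segment_dist(vertices, skeleton$rest_pos[j, ], tip)
      }))
    }
    W[, j] <- exp(-(d / blend_radius)^2)
  }
  mx <- apply(W, 1, max)
  W[W < 1e-3 * mx] <- 0
  W / rowSums(W)
}

#' Build the procedural capsule body
#'
#' Constructs the skeleton and a single connected skin mesh: one closed tube
#' per body chain (torso+head, arms, legs), with each limb tube's proximal
#' cap welded onto the nearest torso vertex, plus smooth distance-based
#' linear-blend skinning weights. Deterministic for a fixed configuration.
#'
#' @param config A [body_config()].
#' @return A list of class `body` with `skeleton` and `mesh` (class
#'   `skinned_mesh`: `vertices` N x 3, `faces` M x 3, `weights` N x 13).
#' @export
build_capsule_body <- function(config = body_config()) {
  skeleton <- build_skeleton(config)
  cfg <- config
  r <- cfg$radii
  res <- as.integer(cfg$resolution)
  pos <- skeleton$rest_pos
  es <- skeleton$end_sites
  acc <- list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3), cap_ids = c())

  # axial spacing scales with resolution so refinement is two-dimensional
  ds_floor <- 0.28 / res
  crotch <- pos["PV", ] + c(0, -0.10, 0)
  torso_line <- rbind(crotch, pos["PV", ], pos["LB", ], pos["T", ], pos["UB", ],
                      pos["NK", ], pos["NK", ] + c(0, 0.5 * cfg$head, 0), es$NK)
  torso_radii <- c(r$torso * 0.92, r$torso, r$waist, r$torso * 0.96, r$torso,
                   r$neck_r, r$head_r, r$head_r * 0.55)
  ds_for <- function(rmean) max(2 * pi * rmean / res, ds_floor)
  acc <- add_tube(acc, torso_line, torso_radii, res, ds_for(r$torso))
  n_torso <- nrow(acc$vertices)

  limb <- function(acc, line, radii, weld_at) {
    weld <- nearest_vertex(acc$vertices[seq_len(n_torso), , drop = FALSE], weld_at)
    add_tube(acc, line, radii, res, ds_for(mean(radii)),
             cap_start = weld, cap_end = "apex")
  }
  acc <- limb(acc, rbind(pos["LS", ], pos["LE", ], es$LE),
              c(r$upper_arm_r, r$forearm_r, r$wrist_r), pos["LS", ])
  acc <- limb(acc, rbind(pos["RS", ], pos["RE", ], es$RE),
              c(r$upper_arm_r, r$forearm_r, r$wrist_r), pos["RS", ])
  acc <- limb(acc, rbind(pos["LT", ], pos["LK", ], es$LK),
              c(r$thigh_r, r$knee_r, r$ankle_r), pos["LT", ])
  acc <- limb(acc, rbind(pos["RT", ], pos["RK", ], es$RK),
              c(r$thigh_r, r$knee_r, r$ankle_r), pos["RT", ])

  weights <- skin_weights(acc$vertices, skeleton, cfg$blend_radius)
  faces <- matrix(as.integer(acc$faces), nrow(acc$faces), 3)
  mesh <- structure(list(vertices = acc$vertices,
                         faces = faces,
                         weights = weights),
                    class = "skinned_mesh")
  structure(list(skeleton = skeleton, mesh = mesh, config = cfg),
            class = "body")
}

#' @export
print.body <- function(x, ...) {
  cat("<body> ", length(x$skeleton$joints), " joints / ",
      length(x$skeleton$dof), " DoF, mesh: ",
      nrow(x$mesh$vertices), " vertices, ", nrow(x$mesh$faces), " faces\n",
      sep = "")
  invisible(x)
}

#' Pose the skin by linear blend skinning
#'
#' Each vertex is the skinning-weighted blend of the joints' rigid transforms
#' applied to its rest position (the bind transform of every joint is a pure
#' translation, since the skeleton's rest orientation is the identity). The
#' identity pose reproduces the rest mesh to machine precision.
#'
#' @param mesh A `skinned_mesh`.
#' @param transforms Per-joint 4x4 world transforms, e.g.
#'   `forward_kinematics(skel, pose)$transforms`.
#' @param skeleton The matching skeleton (for the rest joint positions).
#' @return N x 3 matrix of posed vertex positions.
#' @export
skin_vertices <- function(mesh, transforms, skeleton) {
  if (length(transforms) != ncol(mesh$weights)) {
    stop("expected ", ncol(mesh$weights), " joint transforms, got ",
         length(transforms), call. = FALSE)
  }
  V <- mesh$vertices
  out <- matrix(0, nrow(V), 3)
  for (j in seq_along(transforms)) {
    w <- mesh$weights[, j]
    nz <- w > 0
    if (!any(nz)) next
    Rj <- transforms[[j]][1:3, 1:3]
    tj <- transforms[[j]][1:3, 4]
    bj <- skeleton$rest_pos[j, ]
    moved <- sweep(V[nz, , drop = FALSE], 2, bj) %*% t(Rj)
    moved <- sweep(moved, 2, tj, `+`)
    out[nz, ] <- out[nz, ] + w[nz] * moved
  }
  out
}

#' Surface points
#'
#' A surface point is a face index plus barycentric coordinates on that face.
#'
#' @param face Face index (1-based).
#' @param bary Length-3 nonnegative barycentric weights; normalized to sum 1.
#' @return An object of class `surface_point`.
#' @export
surface_point <- function(face, bary = c(1, 1, 1) / 3) {
  bary <- as.numeric(bary)
  if (length(bary) != 3 || any(bary < -1e-12)) {
    stop("bary must be 3 nonnegative weights", call. = FALSE)
  }
  bary <- pmax(bary, 0)
  structure(list(face = as.integer(face), bary = bary / sum(bary)),
            class = "surface_point")
}

#' @rdname surface_point
#' @param mesh A `skinned_mesh`.
#' @param p A `surface_point`.
#' @param vertices Optional posed vertex matrix (defaults to the rest mesh).
#' @return `surface_point_position()`: the interpolated 3-vector.
#' @export
surface_point_position <- function(mesh, p, vertices = mesh$vertices) {
  if (p$face < 1L || p$face > nrow(mesh$faces)) {
    stop("face index ", p$face, " out of range", call. = FALSE)
  }
  ids <- mesh$faces[p$face, ]
  colSums(p$bary * vertices[ids, , drop = FALSE])
}

# --- mesh diagnostics -------------------------------------------------------

mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Mesh sanity checks
#'
#' @param mesh A `skinned_mesh`.
#' @return List with `connected` (single surface component), `edge_manifold`
#'   (every edge borders at most two faces) and `boundary_edges`.
#' @export
mesh_check <- function(mesh) {
  e <- mesh_edges(mesh$faces)
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  g <- igraph::graph_from_edgelist(unique(e), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  used <- sort(unique(as.vector(mesh$faces)))
  comp <- igraph::components(g)$membership[used]
  list(connected = length(unique(comp)) == 1L,
       edge_manifold = all(cnt <= 2L),
       boundary_edges = sum(cnt == 1L))
}
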