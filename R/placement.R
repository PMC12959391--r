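# Sensor placement by geodesic stretch: enumerate candidate sensor paths on
# the rest skin (grid of centers around each joint x tangent directions),
# score each by the maximal relative length change of its (fixed, material)
# surface path over single-joint sweeps, and greedily keep the top scorers
# subject to a path-proximity overlap rule and per-joint budgets.

vertex_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  # accumulate per-vertex (loop over face corners; small meshes, done once)
  N <- matrix(0, nrow(V), 3)
  for (c in 1:3) {
    idx <- F[, c]
    for (k in 1:3) {
      acc <- rowsum(fn[, k], idx)
      N[as.integer(rownames(acc)), k] <- N[as.integer(rownames(acc)), k] + acc
    }
  }
  len <- sqrt(rowSums(N^2))
  len[len < 1e-12] <- 1
  N / len
}

node_to_surface_point <- function(mesh, geo, node) {
  nV <- geo$n_vertices
  F <- mesh$faces
  if (node <= nV) {
    hits <- which(F == node, arr.ind = TRUE)
    f <- hits[1, "row"]; corner <- hits[1, "col"]
    b <- c(0, 0, 0); b[corner] <- 1
    return(surface_point(f, b))
  }
  comp <- geo$node_comp[node, ]
  u <- comp[1]; v <- comp[2]
  f <- which(rowSums(matrix(F %in% c(u, v), nrow(F), 3)) >= 2)[1]
  b <- as.numeric(F[f, ] %in% c(u, v)) * 0.5
  surface_point(f, b)
}

# Sweep poses that vary only the given joint's DoFs across their ranges.
sweep_poses <- function(skeleton, ranges, joint, n = 9) {
  dofs <- paste(joint, c("X", "Y", "Z"), sep = "_")
  rows <- list()
  for (d in dofs) {
    rg <- range_for(ranges, d)
    vals <- seq(rg[1], rg[2], length.out = n)
    M <- matrix(0, n, length(skeleton$dof),
                dimnames = list(NULL, skeleton$dof))
    M[, d] <- vals
    rows[[d]] <- M
  }
  out <- do.call(rbind, rows)
  out[rowSums(abs(out)) > 0 | seq_len(nrow(out)) == 1, , drop = FALSE]
}

#' Enumerate placement candidates around a joint
#'
#' Candidate sensors are centered on mesh vertices within a geodesic
#' `radius` of the joint, thinned to a minimum spacing, with the tangent
#' direction sampled every `direction_step` degrees (mod 180). Each
#' candidate's endpoints sit a half sensor length away from the center
#' along the surface in the two opposite directions, and its path is the
#' pair of geodesic branches joined at the center.
#'
#' @param body A [build_capsule_body()] result.
#' @param joint Joint name on the skeleton.
#' @param sensor_length Sensor rest length in meters (default 0.16, the
#'   160 mm textile unit).
#' @param grid_spacing Minimum spacing between candidate centers (m).
#' @param direction_step Direction grid step in degrees (default 15, i.e.
#'   12 directions per center).
#' @param radius Geodesic neighborhood radius around the joint (m).
#' @param band_tol Tolerance on the endpoint half-length (m).
#' @param geo Optional precomputed geodesic graph.
#' @return Tibble of candidates: `joint`, `center_vertex`, `direction`
#'   (degrees), `rest_length`, `node_a`, `node_b`, `path` (list of graph
#'   node chains), `enum` (deterministic enumeration index).
#' @export
enumerate_candidates <- function(body, joint, sensor_length = 0.16,
                                 grid_spacing = 0.04, direction_step = 15,
                                 radius = 0.22, band_tol = 0.025,
                                 geo = NULL) {
  stopifnot(sensor_length > 0, grid_spacing > 0, direction_step > 0)
  skeleton <- body$skeleton; mesh <- body$mesh
  if (!joint %in% skeleton$joints) {
    stop("joint ", joint, " is not on the skeleton", call. = FALSE)
  }
  if (is.null(geo)) geo <- build_geodesic_graph(mesh)
  empty <- tibble::tibble(joint = character(), center_vertex = integer(),
                          direction = numeric(), rest_length = numeric(),
                          node_a = integer(), node_b = integer(),
                          path = list(), enum = integer())
  if (radius <= 0) return(empty)
  anchor <- nearest_vertex(mesh$vertices, skeleton$rest_pos[joint, ])
  d_anchor <- geo_dists_from_node(geo, anchor)
  nV <- geo$n_vertices
  cand_centers <- which(d_anchor[seq_len(nV)] <= radius)
  if (length(cand_centers) == 0) return(empty)
  cand_centers <- cand_centers[order(d_anchor[cand_centers], cand_centers)]
  centers <- integer(0)
  for (v in cand_centers) {  # greedy spacing thinning, deterministic
    if (length(centers) == 0 ||
        min(sqrt(rowSums(sweep(mesh$vertices[centers, , drop = FALSE], 2,
                               mesh$vertices[v, ])^2))) >= grid_spacing) {
      centers <- c(centers, v)
    }
  }
  normals <- vertex_normals(mesh)
  half <- sensor_length / 2
  thetas <- seq(0, 180 - direction_step, by = direction_step)
  out <- list()
  for (v in centers) {
    dv <- geo_dists_from_node(geo, v)
    band <- which(abs(dv - half) <= band_tol)
    band <- setdiff(band, v)
    if (length(band) < 2) next
    sp <- igraph::shortest_paths(geo$g, from = v, to = band,
                                 weights = geo$weights, output = "vpath")
    paths <- lapply(sp$vpath, as.integer)
    nrm <- normals[v, ]
    ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    ang <- vapply(paths, function(p) {
      if (length(p) < 2) return(NA_real_)
      d0 <- geo$node_pos[p[2], ] - geo$node_pos[v, ]
      d0 <- d0 - sum(d0 * nrm) * nrm
      (atan2(sum(d0 * e2), sum(d0 * e1)) * 180 / pi) %% 360
    }, 1)
    ok <- !is.na(ang)
    paths <- paths[ok]; band <- band[ok]; ang <- ang[ok]
    if (length(band) < 2) next
    circ <- function(a, b) {
      d <- abs(a - b) %% 360
      pmin(d, 360 - d)
    }
    seen <- character(0)
    for (th in thetas) {
      da <- circ(ang, th); db <- circ(ang, th + 180)
      ia <- which.min(da); ib <- which.min(db)
      if (length(ia) == 0 || length(ib) == 0) next
      if (da[ia] > 25 || db[ib] > 25 || band[ia] == band[ib]) next
      key <- paste(min(band[ia], band[ib]), max(band[ia], band[ib]))
      if (key %in% seen) next
      seen <- c(seen, key)
      path <- c(rev(paths[[ia]])[-length(paths[[ia]])], paths[[ib]])
      out[[length(out) + 1L]] <- tibble::tibble(
        joint = joint, center_vertex = v, direction = th,
        rest_length = dv[band[ia]] + dv[band[ib]],
        node_a = band[ia], node_b = band[ib], path = list(path)
      )
    }
  }
  if (length(out) == 0) return(empty)
  res <- dplyr::bind_rows(out)
  res$enum <- seq_len(nrow(res))
  res
}

# Relative stretch scores for a batch of candidates of one joint.
score_candidates <- function(body, geo, candidates, sweep_angles) {
  if (nrow(candidates) == 0) return(numeric(0))
  cp <- collect_path_points(geo, body$mesh, candidates$path)
  B <- path_basis(cp$pts, body$skeleton)
  L <- path_lengths_batch(B, body$skeleton, sweep_angles, cp$paths)
  L0 <- vapply(cp$paths, function(p) {
    sum(sqrt(rowSums((cp$pts$pos[p[-1], , drop = FALSE] -
                        cp$pts$pos[p[-length(p)], , drop = FALSE])^2)))
  }, 1)
  apply(abs(sweep(L, 2, L0)) / rep(L0, each = nrow(L)), 2, max)
}

#' Stretch score of one placement candidate
#'
#' The maximum over the sweep of the relative change in the candidate
#' path's posed length, `max |L(pose) - L(rest)| / L(rest)`. The path is a
#' fixed material curve on the skin (a sewn sensor cannot re-route), so its
#' posed length is measured by skinning its points.
#'
#' @param body The body.
#' @param candidate One row of [enumerate_candidates()] output.
#' @param sweep_angles Matrix / data frame of sweep poses (rows x 39 DoF).
#' @param geo Optional precomputed geodesic graph.
#' @return Dimensionless score (0 for the rest-pose-only sweep).
#' @export
stretch_score <- function(body, candidate, sweep_angles, geo = NULL) {
  if (is.null(geo)) geo <- build_geodesic_graph(body$mesh)
  A <- as.matrix(as.data.frame(sweep_angles))
  if (nrow(A) == 0) stop("empty sweep", call. = FALSE)
  score_candidates(body, geo, candidate, A)
}

default_sensor_budget <- function() {
  c(PV = 3, LB = 3, T = 3, UB = 3, NK = 2,
    LS = 4, LE = 2, RS = 4, RE = 2,
    LT = 4, LK = 2, RT = 4, RK = 2)
}

#' Design the sensor suit
#'
#' Scores every candidate around every budgeted joint by its stretch over
#' that joint's range sweeps, then greedily accepts candidates in
#' descending score order (ties broken by enumeration order), rejecting any
#' whose surface path comes within `overlap_threshold` of an accepted
#' sensor's path. The default budget places 38 sensors over the 13 joints.
#'
#' @param body The body.
#' @param ranges A `joint_ranges` tibble driving the sweeps.
#' @param per_joint_budget Named vector of sensor counts per joint;
#'   the default totals 38.
#' @param overlap_threshold Minimum distance between sensor paths (m);
#'   default 0.01, one sensor width.
#' @param sensor_length,grid_spacing,direction_step,radius Passed to
#'   [enumerate_candidates()].
#' @param sweep_points Poses per DoF in the scoring sweep.
#' @return An object of class `suit_design`: tibble `sensors` (channel,
#'   joint, score, rest_length, path geometry columns) plus `status`
#'   (`"ok"` or `"partial"`).
#' @export
design_suit <- function(body, ranges = default_joint_ranges(),
                        per_joint_budget = default_sensor_budget(),
                        overlap_threshold = 0.01, sensor_length = 0.16,
                        grid_spacing = 0.04, direction_step = 15,
                        radius = 0.22, sweep_points = 9) {
  stopifnot(all(per_joint_budget >= 1))
  geo <- build_geodesic_graph(body$mesh)
  joints <- names(per_joint_budget)
  all_cand <- list()
  for (jn in joints) {
    cand <- enumerate_candidates(body, jn, sensor_length = sensor_length,
                                 grid_spacing = grid_spacing,
                                 direction_step = direction_step,
                                 radius = radius, geo = geo)
    if (nrow(cand) == 0) next
    sw <- sweep_poses(body$skeleton, ranges, jn, n = sweep_points)
    cand$score <- score_candidates(body, geo, cand, sw)
    all_cand[[jn]] <- cand
  }
  cand <- dplyr::bind_rows(all_cand)
  cand <- cand[order(-cand$score, cand$joint, cand$enum), ]
  budget <- per_joint_budget
  accepted <- list()
  accepted_pts <- matrix(0, 0, 3)
  for (i in seq_len(nrow(cand))) {
    jn <- cand$joint[i]
    if (budget[[jn]] <= 0) next
    pts <- geo$node_pos[cand$path[[i]], , drop = FALSE]
    if (nrow(accepted_pts) > 0) {
      d2min <- min(outer(rowSums(pts^2), rowSums(accepted_pts^2), `+`) -
                     2 * pts %*% t(accepted_pts))
      if (d2min < overlap_threshold^2) next
    }
    budget[[jn]] <- budget[[jn]] - 1
    accepted[[length(accepted) + 1L]] <- cand[i, ]
    accepted_pts <- rbind(accepted_pts, pts)
  }
  sel <- dplyr::bind_rows(accepted)
  status <- if (sum(budget) > 0) "partial" else "ok"
  if (status == "partial") {
    warning("insufficient non-overlapping candidates: placed ",
            nrow(sel), " of ", sum(per_joint_budget), " sensors",
            call. = FALSE)
  }
  sensors <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    nodes <- sel$path[[i]]
    comp <- geo$node_comp[nodes, , drop = FALSE]
    pos <- geo$node_pos[nodes, , drop = FALSE]
    W <- body$mesh$weights[comp[, 1], , drop = FALSE] * comp[, 3] +
      body$mesh$weights[comp[, 2], , drop = FALSE] * comp[, 4]
    tibble::tibble(
      channel = i - 1L,
      joint = sel$joint[i],
      score = sel$score[i],
      rest_length = sel$rest_length[i],
      direction = sel$direction[i],
      center_vertex = sel$center_vertex[i],
      node_a = sel$node_a[i], node_b = sel$node_b[i],
      path_nodes = list(nodes),
      path_comp = list(comp),
      path_pos = list(pos),
      path_w = list(W)
    )
  })
  structure(list(sensors = sensors, status = status,
                 overlap_threshold = overlap_threshold,
                 sensor_length = sensor_length),
            class = "suit_design")
}

#' @export
print.suit_design <- function(x, ...) {
  cat("<suit_design> ", nrow(x$sensors), " sensors over ",
      length(unique(x$sensors$joint)), " joints (status: ", x$status, ")\n",
      sep = "")
  invisible(x)
}

#' Tidy a suit design
#'
#' @param x A `suit_design`.
#' @param ... Unused.
#' @return One row per sensor: channel, joint, score, rest length,
#'   direction.
#' @method tidy suit_design
#' @export
tidy.suit_design <- function(x, ...) {
  dplyr::select(x$sensors, "channel", "joint", "score", "rest_length",
                "direction", "center_vertex")
}

#' Endpoints of a designed sensor as surface points
#'
#' @param body The body the design was made on.
#' @param design A `suit_design`.
#' @param channel Channel id (0-based).
#' @return List of two `surface_point`s.
#' @export
sensor_endpoints <- function(body, design, channel) {
  geo <- build_geodesic_graph(body$mesh)
  s <- design$sensors[design$sensors$channel == channel, ]
  if (nrow(s) != 1) stop("unknown channel ", channel, call. = FALSE)
  list(node_to_surface_point(body$mesh, geo, s$node_a),
       node_to_surface_point(body$mesh, geo, s$node_b))
}
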