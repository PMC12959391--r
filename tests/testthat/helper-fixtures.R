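# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

test_body <- function() memo("body", function() build_capsule_body())

test_design <- function() memo("design", function() design_suit(test_body()))

test_geo <- function() memo("geo", function() {
  build_geodesic_graph(test_body()$mesh)
})

test_hinge <- function() memo("hinge", function() build_hinge_body())

test_hinge_geo <- function() memo("hinge_geo", function() {
  build_geodesic_graph(test_hinge()$mesh)
})

# A short single-joint session bracketed by sync squats, with its simulated
# sensor stream (used by synchronization and IO tests).
sync_fixture <- function() memo("sync", function() {
  body <- test_body(); design <- test_design()
  gen <- single_joint_protocol(seed = 3, segment_s = 6)
  aug <- add_sync_squats(gen$stream, gen$protocol)
  sensors <- simulate_stream(body, design, aug$stream,
                             params = sensor_params(seed = 3))
  list(stream = aug$stream, protocol = aug$protocol, sensors = sensors)
})

# A flat rectangular grid mesh over [0, w] x [0, h] (z = 0), for planar
# geodesic checks.
flat_grid_mesh <- function(nx = 11, ny = 11, w = 10, h = 10) {
  xs <- seq(0, w, length.out = nx)
  ys <- seq(0, h, length.out = ny)
  verts <- as.matrix(expand.grid(x = xs, y = ys))
  verts <- cbind(verts, 0)
  id <- function(i, j) (j - 1L) * nx + i
  faces <- list()
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      faces[[length(faces) + 1L]] <- rbind(
        c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
        c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
      )
    }
  }
  structure(list(vertices = verts, faces = do.call(rbind, faces),
                 weights = NULL),
            class = "skinned_mesh")
}

# Independent O(V^2) Dijkstra on an explicit edge list — the oracle against
# which the igraph-backed geodesic distances are checked exactly.
oracle_dijkstra <- function(n_nodes, edges, weights, source) {
  dist <- rep(Inf, n_nodes)
  done <- rep(FALSE, n_nodes)
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]; w <- weights[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist[source] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (length(u) == 0 || !is.finite(dist[u])) break
    if (done[u]) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (k in seq_len(nrow(nb))) {
        v <- nb[k, 1]
        if (dist[u] + nb[k, 2] < dist[v]) dist[v] <- dist[u] + nb[k, 2]
      }
    }
    if (all(done | !is.finite(dist))) break
  }
  dist
}
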