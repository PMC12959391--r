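test_that("candidates carry the sensor geometry they promise", {
  body <- test_hinge()
  geo <- test_hinge_geo()
  cand <- enumerate_candidates(body, "hinge", geo = geo)
  expect_gt(nrow(cand), 10)
  # rest lengths near the 160 mm unit, within the graph discretization
  expect_true(all(abs(cand$rest_length - 0.16) <= 0.05))
  # directions come from the 15-degree grid (12 slots mod 180)
  grid <- seq(0, 165, by = 15)
  expect_true(all(cand$direction %in% grid))
  expect_lte(length(unique(cand$direction)), 12L)
  expect_gte(length(unique(cand$direction)), 4L)
  # paths run from node_a to node_b
  for (i in c(1, nrow(cand))) {
    p <- cand$path[[i]]
    expect_identical(p[1], cand$node_a[i])
    expect_identical(p[length(p)], cand$node_b[i])
  }
  expect_error(enumerate_candidates(body, "elbow", geo = geo),
               "not on the skeleton")
  none <- enumerate_candidates(body, "hinge", radius = 0, geo = geo)
  expect_identical(nrow(none), 0L)
})

test_that("stretch scores vanish at rest and on rigid segments", {
  body <- test_hinge()
  geo <- test_hinge_geo()
  cand <- enumerate_candidates(body, "hinge", geo = geo)
  rest <- matrix(0, 1, 6, dimnames = list(NULL, body$skeleton$dof))
  s_rest <- stretch_score(body, cand[1, ], rest, geo)
  expect_equal(s_rest, 0, tolerance = 1e-12)
  # a candidate whose path stays on the distal bone moves rigidly with it
  sweep_a <- rest[rep(1, 9), , drop = FALSE]
  sweep_a[, "hinge_X"] <- seq(0, 90, length.out = 9)
  path_y <- vapply(seq_len(nrow(cand)), function(i) {
    range(geo$node_pos[cand$path[[i]], 2])
  }, numeric(2))
  distal <- which(path_y[1, ] > 0.42)[1]
  skip_if(is.na(distal), "no fully distal candidate on this mesh")
  expect_lt(stretch_score(body, cand[distal, ], sweep_a, geo), 1e-3)
})

test_that("the hinge selects a joint-crossing, axis-aligned sensor", {
  body <- test_hinge()
  geo <- test_hinge_geo()
  ranges <- hinge_joint_ranges()
  design <- design_suit(body, ranges, per_joint_budget = c(hinge = 1))
  expect_identical(nrow(design$sensors), 1L)
  s <- design$sensors[1, ]
  # brute force: the accepted sensor is the top-scoring candidate
  cand <- enumerate_candidates(body, "hinge", geo = geo)
  sw <- stretchsuit:::sweep_poses(body$skeleton, ranges, "hinge")
  scores <- stretchsuit:::score_candidates(body, geo, cand, sw)
  expect_equal(s$score, max(scores), tolerance = 1e-12)
  # it crosses the hinge plane (y = 0.3) ...
  ys <- s$path_pos[[1]][, 2]
  expect_lt(min(ys), 0.3)
  expect_gt(max(ys), 0.3)
  # ... and its endpoints separate along the limb (Y) axis
  ends <- s$path_pos[[1]][c(1, nrow(s$path_pos[[1]])), ]
  dirvec <- abs(ends[2, ] - ends[1, ])
  expect_gt(dirvec[2], max(dirvec[1], dirvec[3]))
})

test_that("suit design is deterministic and respects the overlap rule", {
  body <- test_hinge()
  ranges <- hinge_joint_ranges()
  d1 <- design_suit(body, ranges, per_joint_budget = c(hinge = 3))
  d2 <- design_suit(body, ranges, per_joint_budget = c(hinge = 3))
  expect_identical(tidy(d1), tidy(d2))
  # pairwise path distance respects the threshold
  pts <- d1$sensors$path_pos
  for (i in seq_along(pts)) {
    for (j in seq_along(pts)) {
      if (i >= j) next
      d2min <- min(outer(rowSums(pts[[i]]^2), rowSums(pts[[j]]^2), `+`) -
                     2 * pts[[i]] %*% t(pts[[j]]))
      expect_gte(sqrt(max(d2min, 0)), d1$overlap_threshold - 1e-9)
    }
  }
})

test_that("the default full-body design places 38 sensors over 13 joints", {
  design <- test_design()
  expect_identical(design$status, "ok")
  expect_identical(nrow(design$sensors), 38L)
  expect_identical(sort(design$sensors$channel), 0:37)
  expect_identical(length(unique(design$sensors$joint)), 13L)
  expect_true(all(design$sensors$rest_length > 0))
  # serialization round trip
  f <- withr::local_tempfile(fileext = ".json")
  write_suit_design(design, f)
  back <- read_suit_design(f)
  expect_equal(tidy(back), tidy(design), tolerance = 1e-9)
  expect_equal(back$sensors$path_pos[[5]], design$sensors$path_pos[[5]],
               tolerance = 1e-9)
})

test_that("sensor endpoints resolve to surface points at the path ends", {
  body <- test_hinge()
  design <- design_suit(body, hinge_joint_ranges(),
                        per_joint_budget = c(hinge = 1))
  eps <- sensor_endpoints(body, design, 0L)
  p1 <- surface_point_position(body$mesh, eps[[1]])
  p2 <- surface_point_position(body$mesh, eps[[2]])
  path <- design$sensors$path_pos[[1]]
  expect_equal(as.numeric(p1), path[1, ], tolerance = 1e-9)
  expect_equal(as.numeric(p2), path[nrow(path), ], tolerance = 1e-9)
})
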