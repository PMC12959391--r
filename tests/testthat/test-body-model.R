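test_that("default body has 13 joints, 39 DoF, and a clean skin", {
  body <- test_body()
  sk <- body$skeleton
  expect_length(sk$joints, 13)
  expect_length(sk$dof, 39)
  expect_true(all(MOCAP_JOINT_ORDER %in% sk$joints))
  # parent indices form a tree rooted at the pelvis
  expect_identical(sum(sk$parent == 0L), 1L)
  expect_identical(sk$joints[sk$parent == 0L], "PV")
  for (j in seq_along(sk$joints)[-1]) expect_lt(sk$parent[j], j)
  chk <- mesh_check(body$mesh)
  expect_true(chk$connected)
  expect_true(chk$edge_manifold)
  expect_identical(chk$boundary_edges, 0L)
  expect_equal(rowSums(body$mesh$weights), rep(1, nrow(body$mesh$vertices)),
               tolerance = 1e-9)
})

test_that("doubling the mesh resolution scales faces ~4x, same skeleton", {
  b1 <- test_body()
  b2 <- build_capsule_body(body_config(resolution = 20))
  expect_equal(b2$skeleton$rest_pos, b1$skeleton$rest_pos)
  ratio <- nrow(b2$mesh$faces) / nrow(b1$mesh$faces)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("non-positive dimensions are rejected", {
  expect_error(body_config(upper_arm = -0.1), "positive")
  expect_error(body_config(resolution = 4), "at least 8")
})

test_that("forward kinematics matches closed-form rotations", {
  body <- test_body()
  sk <- body$skeleton
  fk0 <- forward_kinematics(sk, rest_pose(sk))
  expect_equal(fk0$positions, sk$rest_pos, tolerance = 1e-12)
  # 90 deg elbow flexion about X: the forearm end site rotates in the Y-Z
  # plane around the elbow
  p <- rest_pose(sk)
  p["LE_X"] <- 90
  fk <- forward_kinematics(sk, p)
  elbow <- sk$rest_pos["LE", ]
  wrist_rest <- sk$end_sites$LE
  arm <- wrist_rest - elbow
  expected <- elbow + c(arm[1], -arm[3], arm[2])  # Rx(90): (x, -z, y)
  # apply the elbow transform to the wrist expressed in bind space
  w <- fk$transforms$LE[1:3, 1:3] %*% (wrist_rest - elbow) +
    fk$transforms$LE[1:3, 4]
  expect_equal(as.numeric(w), as.numeric(expected), tolerance = 1e-12)
  expect_error(forward_kinematics(sk, rep(0, 10)), "DoF")
})

test_that("joint rotations are orthonormal and invert cleanly", {
  sk <- test_body()$skeleton
  set.seed(11)
  for (rep in 1:5) {
    p <- stats::setNames(runif(39, -60, 60), sk$dof)
    fk <- forward_kinematics(sk, p)
    for (j in sk$joints) {
      R <- fk$transforms[[j]][1:3, 1:3]
      expect_equal(R %*% t(R), diag(3), tolerance = 1e-12)
      expect_equal(det(R), 1, tolerance = 1e-12)
    }
    # intrinsic X-Y-Z composed with its reversed negation is the identity
    a <- p[1]; b <- p[2]; c <- p[3]
    R <- matrix(stretchsuit:::rot_xyz_batch(a, b, c), 3, 3)
    Rz <- matrix(stretchsuit:::rot_xyz_batch(0, 0, -c), 3, 3)
    Ry <- matrix(stretchsuit:::rot_xyz_batch(0, -b, 0), 3, 3)
    Rx <- matrix(stretchsuit:::rot_xyz_batch(-a, 0, 0), 3, 3)
    expect_equal(R %*% Rz %*% Ry %*% Rx, diag(3), tolerance = 1e-12)
  }
})

test_that("skinning reproduces the rest mesh and follows rigid joints", {
  body <- test_body()
  sk <- body$skeleton
  fk0 <- forward_kinematics(sk, rest_pose(sk))
  posed <- skin_vertices(body$mesh, fk0$transforms, sk)
  expect_lt(max(abs(posed - body$mesh$vertices)), 1e-12)
  # a vertex fully bound to one joint follows that joint's transform exactly
  set.seed(21)
  p <- stats::setNames(runif(39, -40, 40), sk$dof)
  fk <- forward_kinematics(sk, p)
  posed <- skin_vertices(body$mesh, fk$transforms, sk)
  for (j in seq_along(sk$joints)) {
    rigid <- which(body$mesh$weights[, j] == 1)
    if (length(rigid) == 0) next
    i <- rigid[1]
    v <- body$mesh$vertices[i, ]
    expected <- fk$transforms[[j]][1:3, 1:3] %*% (v - sk$rest_pos[j, ]) +
      fk$transforms[[j]][1:3, 4]
    expect_equal(posed[i, ], as.numeric(expected), tolerance = 1e-12)
  }
  expect_error(skin_vertices(body$mesh, fk$transforms[1:5], sk), "transforms")
})

test_that("a root rotation moves the whole skin rigidly", {
  body <- test_body()
  sk <- body$skeleton
  p <- rest_pose(sk)
  p["PV_X"] <- 30; p["PV_Y"] <- -20; p["PV_Z"] <- 45
  fk <- forward_kinematics(sk, p)
  posed <- skin_vertices(body$mesh, fk$transforms, sk)
  R <- fk$transforms$PV[1:3, 1:3]
  pivot <- sk$rest_pos["PV", ]
  expected <- sweep(sweep(body$mesh$vertices, 2, pivot) %*% t(R), 2, pivot, `+`)
  expect_equal(posed, expected, tolerance = 1e-9)
})

test_that("pose flattening round-trips all 39 DoF", {
  sk <- test_body()$skeleton
  set.seed(5)
  p <- stats::setNames(runif(39, -170, 170), sk$dof)
  m <- pose_matrix(sk, p)
  back <- as_pose(sk, stats::setNames(as.vector(t(m)), sk$dof))
  expect_identical(back, as_pose(sk, p))
  expect_error(as_pose(sk, c(p[-1], BAD = 200)), NA) # unknown names ignored
  expect_error(as_pose(sk, rep(200, 39)), "180")
})

test_that("surface points interpolate their faces", {
  body <- test_body()
  mesh <- body$mesh
  f <- 10L
  ids <- mesh$faces[f, ]
  expect_equal(surface_point_position(mesh, surface_point(f, c(1, 0, 0))),
               mesh$vertices[ids[1], ])
  expect_equal(surface_point_position(mesh, surface_point(f)),
               colMeans(mesh$vertices[ids, ]))
  expect_error(surface_point_position(mesh, surface_point(10^7)),
               "out of range")
  expect_error(surface_point(1, c(-1, 1, 1)), "nonnegative")
})

test_that("OBJ export and import round-trip the rest mesh", {
  body <- test_hinge()
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(body$mesh, path)
  back <- read_obj(path)
  expect_equal(back$vertices, body$mesh$vertices, tolerance = 1e-7)
  expect_identical(back$faces, body$mesh$faces)
})
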