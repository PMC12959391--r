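test_that("the gauge law matches its closed forms", {
  p <- sensor_params(c_base = 100, gauge = 0.8, c_trace = 0, noise_sd = 0)
  expect_equal(capacitance_response(0, 0, p), 100)
  expect_equal(capacitance_response(0.25, 0, p), 120)
  expect_gt(capacitance_response(0.5, 0, p), capacitance_response(0, 0, p))
  # strictly increasing for s >= 0, non-decreasing below
  s <- seq(-0.05, 0.5, by = 0.01)
  C <- capacitance_response(s, 0, p)
  expect_true(all(diff(C) >= 0))
  expect_true(all(diff(C[s[-1] > 0]) > 0))
  expect_error(capacitance_response(-0.5, 0, p), "floor")
  expect_error(sensor_params(gauge = -1), "gauge")
})

test_that("strain is zero at rest and under rigid whole-body motion", {
  body <- test_body()
  design <- test_design()
  sk <- body$skeleton
  fk0 <- forward_kinematics(sk, rest_pose(sk))
  v0 <- skin_vertices(body$mesh, fk0$transforms, sk)
  s0 <- sensor_strain(design, v0)
  expect_equal(s0, rep(0, 38), tolerance = 1e-9)
  # rotating the root is an isometry of the whole skin
  p <- rest_pose(sk); p["PV_Y"] <- 40; p["PV_X"] <- -15
  fk <- forward_kinematics(sk, p)
  v1 <- skin_vertices(body$mesh, fk$transforms, sk)
  expect_equal(sensor_strain(design, v1), rep(0, 38), tolerance = 1e-9)
  # a deep squat deforms at least one knee-associated path strongly
  # (unclamped, since the selected knee sensors may sit on the buckling side)
  p2 <- rest_pose(sk); p2["LK_X"] <- 110; p2["RK_X"] <- 110
  fk2 <- forward_kinematics(sk, p2)
  v2 <- skin_vertices(body$mesh, fk2$transforms, sk)
  s2 <- sensor_strain(design, v2, strain_floor = -1)
  knees <- design$sensors$joint %in% c("LK", "RK")
  expect_gt(max(abs(s2[knees])), 0.05)
  # the clamp floor is honored by the default
  expect_gte(min(sensor_strain(design, v2)), -0.05)
})

test_that("streams have 38 ordered channels and are seed-reproducible", {
  body <- test_body(); design <- test_design()
  stream <- multijoint_routine(duration_s = 6, seed = 2)
  s1 <- simulate_stream(body, design, stream, params = sensor_params(seed = 5))
  s2 <- simulate_stream(body, design, stream, params = sensor_params(seed = 5))
  expect_identical(s1, s2)
  expect_identical(stream_channels(s1), sprintf("ch%02d", 0:37))
  expect_equal(stream_rate(s1), 40, tolerance = 1e-9)
  expect_true(all(as.matrix(s1[, -1]) > 0))
  s3 <- simulate_stream(body, design, stream, params = sensor_params(seed = 6))
  expect_false(identical(s1, s3))
})

test_that("a constant pose yields a constant noise-free stream", {
  body <- test_body(); design <- test_design()
  dofs <- body$skeleton$dof
  A <- matrix(15, 200, 39, dimnames = list(NULL, dofs))
  stream <- stretchsuit:::angle_stream_tbl((0:199) / 100, A, dofs)
  out <- simulate_stream(body, design, stream,
                         params = sensor_params(noise_sd = 0))
  M <- as.matrix(out[, -1])
  expect_lt(max(apply(M, 2, function(x) diff(range(x)))), 1e-9)
})

test_that("decimating an 80 Hz simulation reproduces the 40 Hz one", {
  body <- test_body(); design <- test_design()
  stream <- multijoint_routine(duration_s = 4, seed = 3)
  p <- sensor_params(noise_sd = 0)
  s40 <- simulate_stream(body, design, stream, params = p, rate = 40)
  s80 <- simulate_stream(body, design, stream, params = p, rate = 80)
  shared <- seq(1, nrow(s80), by = 2)[seq_len(nrow(s40))]
  expect_equal(as.matrix(s80[shared, -1]), as.matrix(s40[, -1]),
               tolerance = 1e-9)
})

test_that("per-channel noise substreams are reproducible and uncorrelated", {
  body <- test_body(); design <- test_design()
  dofs <- body$skeleton$dof
  A <- matrix(0, 4000, 39, dimnames = list(NULL, dofs))
  stream <- stretchsuit:::angle_stream_tbl((0:3999) / 100, A, dofs)
  out <- simulate_stream(body, design, stream,
                         params = sensor_params(noise_sd = 0.5, seed = 11))
  M <- scale(as.matrix(out[, -1]), scale = FALSE)
  cors <- stats::cor(M)
  off_diag <- abs(cors[upper.tri(cors)])
  expect_lt(max(off_diag), 0.12)
})

test_that("drift propagates outward from the armpits and knees", {
  body <- test_body(); design <- test_design()
  model <- drift_model(onset_time = 30, propagation_speed = 0.002,
                       max_drift = 6, tau = 120)
  field <- build_drift_field(body, design, model)
  on <- field$onsets
  expect_true(all(drift_values(field, 0, on$channel) == 0))
  expect_true(all(drift_values(field, c(0, 10, 20), on$channel) == 0))
  # armpit/knee-adjacent channels lead distal ones
  near <- on$channel[which.min(on$distance)]
  far <- on$channel[which.max(on$distance)]
  expect_lt(on$onset_s[on$channel == near], on$onset_s[on$channel == far])
  # monotone, saturating rise
  tt <- seq(0, 3000, by = 25)
  dv <- drift_values(field, tt, near)
  expect_true(all(diff(dv) >= -1e-12))
  expect_lte(max(dv), model$max_drift)
  # zero amplitude kills the field
  f0 <- build_drift_field(body, design, drift_model(max_drift = 0))
  expect_equal(max(abs(drift_values(f0, tt, on$channel))), 0)
  expect_error(drift_model(seed_regions = "left_elbow"), "unknown")
})
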