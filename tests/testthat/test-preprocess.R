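test_that("linear resampling preserves constants, ramps and endpoints", {
  const <- tibble::tibble(time_s = (0:39) / 40, a = 5)
  up <- resample_linear(const, 100)
  expect_true(all(up$a == 5))
  expect_equal(stream_rate(up), 100, tolerance = 1e-9)
  ramp <- tibble::tibble(time_s = c(0, 1), a = c(0, 1))
  mid <- resample_linear(ramp, 2)
  expect_equal(mid$a[mid$time_s == 0.5], 0.5)
  expect_equal(mid$a[1], 0)
  expect_equal(mid$a[nrow(mid)], 1)
  bad <- tibble::tibble(time_s = c(0, 2, 1), a = 1:3)
  expect_error(resample_linear(bad), "increasing")
})

test_that("down-up resampling error stays under the interpolation bound", {
  t100 <- (0:499) / 100
  x <- tibble::tibble(time_s = t100, a = sin(2 * pi * 1 * t100))
  down <- resample_linear(x, 40)
  up <- resample_linear(down, 100)
  n <- nrow(up)
  err <- max(abs(up$a - x$a[seq_len(n)]))
  bound <- (1 / 40)^2 * pi^2 / 2          # (f dt)^2 pi^2 / 2 at f = 1 Hz
  # the down-step interpolates too (40 Hz knots are off the 100 Hz grid),
  # compounding the single-stage bound by a few percent
  expect_lt(err, 1.05 * bound)
})

test_that("the zero-phase Butterworth matches its magnitude response", {
  t <- (0:2999) / 100
  dc <- tibble::tibble(time_s = t, a = rep(3, length(t)))
  expect_equal(lowpass_reference(dc)$a, dc$a, tolerance = 1e-6)
  mk <- function(f) tibble::tibble(time_s = t, a = sin(2 * pi * f * t))
  mid <- 1000:2000
  # 1 Hz passband: preserved within 1%
  y1 <- lowpass_reference(mk(1))$a
  expect_lt(abs(max(abs(y1[mid])) - 1), 0.01)
  # 20 Hz stopband: single-pass ratio 1/sqrt(1 + (20/10)^8) ~ 0.0624,
  # squared by the forward-backward pass
  y20 <- lowpass_reference(mk(20))$a
  ratio <- max(abs(y20[mid]))
  expect_lt(ratio, 2.5 * 0.0624^2)
  expect_gt(ratio, 0.2 * 0.0624^2)
  slow <- tibble::tibble(time_s = (0:99) / 15, a = rnorm(100))
  expect_error(lowpass_reference(slow), "too low")
})

test_that("3:1:1 splits have exact sizes and are reproducible", {
  d <- tibble::tibble(time_s = (0:38699) / 100, x = 0)
  s1 <- split_dataset(d, mode = "random", seed = 3)
  expect_identical(as.integer(table(s1$split)), c(23220L, 7740L, 7740L))
  s2 <- split_dataset(d, mode = "random", seed = 3)
  expect_identical(s1$split, s2$split)
  expect_false(identical(s1$split, split_dataset(d, seed = 4)$split))
  # sequential (unlabeled): train < val < test in time
  sq <- split_dataset(d, mode = "sequential")
  expect_lt(max(sq$time_s[sq$split == "train"]), min(sq$time_s[sq$split == "val"]))
  expect_lt(max(sq$time_s[sq$split == "val"]), min(sq$time_s[sq$split == "test"]))
  # sequential with labels: per-segment ordering
  d$label <- rep(c("a", "b"), each = 19350)
  sql <- split_dataset(d, mode = "sequential")
  for (cl in c("a", "b")) {
    seg <- sql[sql$label == cl, ]
    expect_lt(max(seg$time_s[seg$split == "train"]),
              min(seg$time_s[seg$split == "test"]))
    expect_identical(as.integer(table(seg$split)), c(11610L, 3870L, 3870L))
  }
  expect_error(split_dataset(d[1:3, ]), "at least 5")
})

test_that("min-max normalization hits [0, 1] and ignores affine rescaling", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(8)
  x <- rnorm(50)
  y <- minmax_normalize(x)
  expect_equal(range(y), c(0, 1))
  expect_equal(minmax_normalize(3.7 * x + 11), y, tolerance = 1e-12)
  expect_error(minmax_normalize(rep(1, 5)), "constant")
})

test_that("summed angle-change rate counts every DoF's motion", {
  sk <- test_body()$skeleton
  A <- matrix(0, 100, 39, dimnames = list(NULL, sk$dof))
  s0 <- stretchsuit:::angle_stream_tbl((0:99) / 100, A, sk$dof)
  expect_equal(attr(summed_angle_change_rate(s0), "mean_rate"), 0)
  A[, "LE_X"] <- seq(0, 0.99, by = 0.01) * 100  # 1 deg per 10 ms frame
  s1 <- stretchsuit:::angle_stream_tbl((0:99) / 100, A, sk$dof)
  r <- summed_angle_change_rate(s1)
  expect_equal(unique(round(r$rate_deg_per_10ms, 9)), 1)
})

test_that("squat synchronization recovers offsets within one frame", {
  fx <- sync_fixture()
  design <- test_design()
  set.seed(31)
  offsets <- c(0, 1.37, round(runif(8, -3, 3), 3))
  errs <- vapply(offsets, function(off) {
    shifted <- fx$sensors
    shifted$time_s <- fx$sensors$time_s - off
    out <- synchronize_streams(shifted, fx$stream, design = design)
    abs(attr(out, "offset_s") - off)
  }, 1)
  expect_lt(max(errs), 0.010)        # one 100 Hz frame
  # zero offset: identity alignment
  out0 <- synchronize_streams(fx$sensors, fx$stream, design = design)
  expect_lt(abs(attr(out0, "offset_s")), 0.010)
  expect_equal(attr(out0, "clock_scale"), 1, tolerance = 1e-4)
})

test_that("squat synchronization recovers an injected clock drift", {
  fx <- sync_fixture()
  design <- test_design()
  shifted <- fx$sensors
  shifted$time_s <- (fx$sensors$time_s - 1.1) / 1.001   # 0.1% clock drift
  out <- synchronize_streams(shifted, fx$stream, design = design)
  expect_lt(abs(attr(out, "clock_scale") - 1.001), 1e-4) # within 0.01%
  expect_lt(abs(attr(out, "offset_s") - 1.1), 0.010)
  # aligned table carries both channels and DoF columns on one clock
  expect_true(all(c("ch00", "LK_X", "time_s") %in% names(out)))
})

test_that("synchronization fails loudly without squat bursts", {
  fx <- sync_fixture()
  design <- test_design()
  flat <- fx$stream
  for (d in stream_dofs(flat)) flat[[d]] <- 0
  expect_error(synchronize_streams(fx$sensors, flat, design = design),
               "squat")
})
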