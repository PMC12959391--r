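peak_count <- function(x, height) {
  pk <- pracma::findpeaks(x, minpeakheight = height,
                          peakpat = "[+]{1,}[0]*[-]{1,}")
  if (is.null(pk)) 0L else nrow(pk)
}

test_that("single-joint protocol follows the standard joint order and timing", {
  gen <- single_joint_protocol(seed = 1)
  lab <- gen$protocol$label
  expect_length(lab, 33)
  joints <- unique(sub("_[XYZ]$", "", lab))
  expect_identical(joints, MOCAP_JOINT_ORDER)
  expect_identical(sub("^.*_", "", lab[1:3]), c("X", "Y", "Z"))
  total <- max(gen$protocol$end_s)
  expect_lt(abs(total - 387), 5)                       # ~387 s session
  expect_lt(abs(nrow(gen$stream) - 38700), 500)        # ~38,700 frames
})

test_that("each sweep segment shows five peaks on its target DoF", {
  gen <- single_joint_protocol(seed = 1, reps = 5)
  ranges <- default_joint_ranges()
  for (i in c(1, 17, 33)) {
    seg <- gen$protocol[i, ]
    rows <- gen$stream$time_s >= seg$start_s & gen$stream$time_s < seg$end_s
    x <- gen$stream[[seg$label]][rows]
    rg <- c(ranges$lo[ranges$dof == seg$label],
            ranges$hi[ranges$dof == seg$label])
    thresh <- mean(rg) + 0.8 * diff(rg) / 2
    expect_identical(peak_count(x, thresh), 5L)
  }
})

test_that("generated angles always respect the configured ranges", {
  ranges <- default_joint_ranges()
  streams <- list(
    single_joint_protocol(seed = 2, segment_s = 3)$stream,
    multijoint_routine(duration_s = 30, seed = 2),
    pick_place_protocol(segment_s = 5, seed = 2)$stream,
    gait_protocol(segment_s = 5, seed = 2)$stream
  )
  for (s in streams) {
    for (i in seq_len(nrow(ranges))) {
      x <- s[[ranges$dof[i]]]
      expect_gte(min(x), ranges$lo[i] - 1e-9)
      expect_lte(max(x), ranges$hi[i] + 1e-9)
    }
  }
})

test_that("the multijoint routine hits its angle-change-rate target", {
  for (target in c(15.9, 3.9)) {
    s <- multijoint_routine(duration_s = 60, target_rate = target, seed = 4)
    rate <- attr(summed_angle_change_rate(s), "mean_rate")
    expect_lt(abs(rate - target) / target, 0.1)
  }
  s0 <- multijoint_routine(duration_s = 10, target_rate = 0, seed = 4)
  expect_equal(attr(summed_angle_change_rate(s0), "mean_rate"), 0)
  expect_error(multijoint_routine(duration_s = 10, target_rate = 500, seed = 4),
               "unreachable")
})

test_that("pick-and-place classes pace themselves by the metronome", {
  gen <- pick_place_protocol(segment_s = 40, seed = 5)
  expect_identical(nrow(gen$protocol), 15L)
  dominant_freq <- function(label) {
    seg <- gen$protocol[gen$protocol$label == label, ]
    rows <- gen$stream$time_s >= seg$start_s & gen$stream$time_s < seg$end_s
    prof <- frequency_profile(gen$stream$LE_X[rows], rate = 100)
    dominant_components(prof, 1)$frequency_hz
  }
  f10 <- dominant_freq("upper_1.0x")
  expect_lt(abs(f10 - 90 / 60 / 2), 0.05)     # one reach half-cycle per beat
  f06 <- dominant_freq("upper_0.6x")
  f14 <- dominant_freq("upper_1.4x")
  expect_lt(abs(f14 / f06 - 7 / 3), 0.15)
})

test_that("gait classes are 15, labeled consistently, cadence rises with speed", {
  gen <- gait_protocol(segment_s = 30, seed = 6)  # 1/30 Hz FFT resolution
  expect_identical(nrow(gen$protocol), 15L)
  expect_identical(anyDuplicated(gen$protocol$label), 0L)
  lab <- protocol_labels(gen$stream$time_s, gen$protocol)
  expect_true(all(table(lab) > 0))
  f <- vapply(sprintf("speed_%.1fx", c(0.6, 0.8, 1.0, 1.2)), function(cl) {
    seg <- gen$protocol[gen$protocol$label == cl, ]
    rows <- gen$stream$time_s >= seg$start_s & gen$stream$time_s < seg$end_s
    dominant_components(
      frequency_profile(gen$stream$LT_X[rows], rate = 100), 1)$frequency_hz
  }, 1)
  expect_true(all(diff(f) > 0))
})

test_that("sync squats bracket the stream with detectable knee peaks", {
  gen <- gait_protocol(widths = character(0), slopes = integer(0),
                       segment_s = 10, seed = 7)
  aug <- add_sync_squats(gen$stream, gen$protocol, n = 5)
  lead <- min(aug$protocol$start_s)
  expect_equal(lead, 5 * 1.2 + 1)
  core <- aug$stream$time_s >= lead &
    aug$stream$time_s < max(aug$protocol$end_s)
  outside <- aug$stream$LK_X[!core]
  expect_identical(peak_count(outside, 60), 10L)   # 2n peaks, 60 deg prominence
  same <- add_sync_squats(gen$stream, gen$protocol, n = 0)
  expect_identical(same$stream, gen$stream)
})

test_that("every generator is deterministic under a fixed seed", {
  expect_identical(single_joint_protocol(seed = 9, segment_s = 2),
                   single_joint_protocol(seed = 9, segment_s = 2))
  expect_identical(multijoint_routine(duration_s = 5, seed = 9),
                   multijoint_routine(duration_s = 5, seed = 9))
  expect_identical(gait_protocol(segment_s = 2, seed = 9),
                   gait_protocol(segment_s = 2, seed = 9))
  expect_identical(pick_place_protocol(segment_s = 2, seed = 9),
                   pick_place_protocol(segment_s = 2, seed = 9))
})
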