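# Scripted, labeled synthetic motion protocols at 100 Hz: a daily-pose corpus
# for range statistics, single-joint sweep sessions, a calisthenics-like
# multijoint routine, periodic pick-and-place reaches, and treadmill gait
# with speed / step-width / slope signatures. Every generator is seeded and
# deterministic, and all angles respect the configured joint ranges.

#' Synthetic daily-pose corpus
#'
#' Draws poses per-DoF from truncated normal distributions centered on the
#' middle of each configured range (sd = a quarter of the range width), a
#' light-tailed stand-in for a large daily-activity pose corpus.
#'
#' @param ranges A `joint_ranges` tibble (see [default_joint_ranges()]).
#' @param n Number of poses.
#' @param seed Integer seed.
#' @return Tibble with `n` rows and one column per DoF (degrees).
#' @export
sample_pose_corpus <- function(ranges = default_joint_ranges(), n = 1000,
                               seed = 1) {
  stopifnot(n >= 1)
  with_seed(seed, {
    cols <- purrr::map(seq_len(nrow(ranges)), function(i) {
      lo <- ranges$lo[i]; hi <- ranges$hi[i]
      mid <- (lo + hi) / 2; sd <- (hi - lo) / 4
      # inverse-CDF truncated normal: exact support, no rejection loop
      u <- stats::runif(n, stats::pnorm(lo, mid, sd), stats::pnorm(hi, mid, sd))
      pmin(hi, pmax(lo, stats::qnorm(u, mid, sd)))
    })
    names(cols) <- ranges$dof
    tibble::as_tibble(cols)
  })
}

#' Single-joint sweep protocol
#'
#' For each of the 11 optically tracked joints, in the standard order
#' LE, LS, RE, RS, UB, LB, T, LT, RT, LK, RK, and for each axis X, Y, Z,
#' the target DoF performs `reps` smooth sinusoidal sweeps across its
#' configured range while every other DoF carries small seeded jitter
#' (the wearer is not required to hold other joints still). Labeled one
#' segment per (joint, axis).
#'
#' @param ranges A `joint_ranges` tibble.
#' @param reps Sweeps per segment (default 5).
#' @param seed Integer seed.
#' @param segment_s Segment duration in seconds; the default 11.7 s gives a
#'   session of about 387 s over the 33 segments.
#' @param rate Frame rate in Hz (100).
#' @param jitter_amp Jitter amplitude on non-target DoFs (degrees).
#' @return List with `stream` (angle tibble, `time_s` + 39 DoF columns) and
#'   `protocol` (segment tibble).
#' @export
single_joint_protocol <- function(ranges = default_joint_ranges(), reps = 5,
                                  seed = 1, segment_s = 11.7, rate = 100,
                                  jitter_amp = 2) {
  skeleton <- build_skeleton()
  dofs <- skeleton$dof
  segs <- expand.grid(axis = c("X", "Y", "Z"), joint = MOCAP_JOINT_ORDER,
                      stringsAsFactors = FALSE)[, c("joint", "axis")]
  n_seg <- nrow(segs)
  nT_seg <- round(segment_s * rate)
  nT <- n_seg * nT_seg
  times <- (seq_len(nT) - 1) / rate
  with_seed(seed, {
    A <- matrix(0, nT, length(dofs))
    # background jitter everywhere, kept inside each DoF's range
    for (k in seq_along(dofs)) {
      rg <- range_for(ranges, dofs[k])
      base <- min(max(0, rg[1] + jitter_amp), rg[2] - jitter_amp)
      A[, k] <- base + smooth_jitter(times, jitter_amp)
    }
    for (i in seq_len(n_seg)) {
      d <- paste(segs$joint[i], segs$axis[i], sep = "_")
      k <- match(d, dofs)
      rg <- range_for(ranges, d)
      mid <- (rg[1] + rg[2]) / 2; half <- (rg[2] - rg[1]) / 2
      rows <- (i - 1L) * nT_seg + seq_len(nT_seg)
      tl <- times[rows] - times[rows[1]]
      A[rows, k] <- mid + half * sin(2 * pi * reps * tl / segment_s)
    }
    A <- clip_to_ranges(A, dofs, ranges)
    stream <- angle_stream_tbl(times, A, dofs)
    protocol <- protocol_tbl(
      start_s = (seq_len(n_seg) - 1) * segment_s,
      end_s = seq_len(n_seg) * segment_s,
      label = paste(segs$joint, segs$axis, sep = "_")
    )
    list(stream = stream, protocol = protocol)
  })
}

#' Calisthenics-like multijoint routine
#'
#' A coordinated whole-body routine: a small set of shared latent
#' oscillators (multi-frequency sinusoids) is mixed across all DoFs, the
#' way scripted calisthenics move many joints in a few coordinated
#' patterns rather than independently. One global amplitude factor is
#' solved so that the mean summed angle-change rate (degrees per 10 ms,
#' summed over all 39 DoF) matches `target_rate`; the factor enters
#' linearly, so the match is exact up to range clipping.
#'
#' @param ranges A `joint_ranges` tibble.
#' @param duration_s Routine length in seconds (default 240, a 4-minute
#'   routine).
#' @param target_rate Mean summed angle-change rate in degrees per 10 ms.
#' @param seed Integer seed.
#' @param rate Frame rate (Hz).
#' @param n_harmonics Sinusoids per latent oscillator.
#' @param latent_dim Number of shared oscillators (coordination
#'   dimensionality of the routine).
#' @return An angle-stream tibble.
#' @export
multijoint_routine <- function(ranges = default_joint_ranges(),
                               duration_s = 240, target_rate = 15.9,
                               seed = 1, rate = 100, n_harmonics = 2,
                               latent_dim = 8) {
  stopifnot(duration_s > 0, target_rate >= 0, latent_dim >= 1)
  skeleton <- build_skeleton()
  dofs <- skeleton$dof
  nT <- round(duration_s * rate)
  times <- (seq_len(nT) - 1) / rate
  with_seed(seed, {
    Z <- matrix(0, nT, latent_dim)
    for (k in seq_len(latent_dim)) {
      # calisthenics tempo: movement primitives around 0.3-1 Hz
      f <- stats::runif(n_harmonics, 0.3, 1.0)
      ph <- stats::runif(n_harmonics, 0, 2 * pi)
      cc <- stats::runif(n_harmonics, 0.3, 1)
      cc <- cc / sum(cc)
      for (h in seq_len(n_harmonics)) {
        Z[, k] <- Z[, k] + cc[h] * sin(2 * pi * f[h] * times + ph[h])
      }
    }
    # each DoF follows a sparse mix of the latent oscillators
    W <- matrix(0, length(dofs), latent_dim)
    for (d in seq_along(dofs)) {
      picks <- sample.int(latent_dim, min(3L, latent_dim))
      W[d, picks] <- stats::runif(length(picks), 0.3, 1) *
        sample(c(-1, 1), length(picks), replace = TRUE)
    }
    U <- Z %*% t(W)
    U <- sweep(U, 2, pmax(apply(abs(U), 2, max), 1e-9), `/`)
    half <- (ranges$hi[match(dofs, ranges$dof)] -
               ranges$lo[match(dofs, ranges$dof)]) / 2
    mid <- (ranges$hi[match(dofs, ranges$dof)] +
              ranges$lo[match(dofs, ranges$dof)]) / 2
    scaled <- sweep(U, 2, half, `*`)
    base_rate <- mean(rowSums(abs(apply(scaled, 2, diff))))
    if (base_rate <= 0 && target_rate > 0) {
      stop("degenerate routine: zero base motion", call. = FALSE)
    }
    alpha <- if (target_rate == 0) 0 else target_rate / base_rate
    if (alpha > 1) {
      stop("target_rate ", target_rate,
           " deg/10ms is unreachable within the configured joint ranges",
           call. = FALSE)
    }
    A <- sweep(alpha * scaled, 2, mid, `+`)
    A <- clip_to_ranges(A, dofs, ranges)
    angle_stream_tbl(times, A, dofs)
  })
}

#' Periodic pick-and-place reach protocol
#'
#' Repeated reaches to the left and right at three heights and five
#' metronome-paced speeds (one reach half-cycle per beat, base 90 BPM), one
#' labeled segment per height x speed class. The joint allocation follows
#' the observed pattern: upper height loads the shoulders more than the
#' elbows, middle height predominantly the elbows, and lower height the
#' elbows slightly more than the shoulders.
#'
#' @param heights Height classes.
#' @param speeds Speed multipliers of the 90 BPM base.
#' @param bpm_base Metronome base rate (beats per minute).
#' @param segment_s Duration of each class segment (seconds).
#' @param seed Integer seed.
#' @param rate Frame rate (Hz).
#' @param ranges A `joint_ranges` tibble.
#' @return List with `stream` and `protocol` (15 classes by default).
#' @export
pick_place_protocol <- function(heights = c("upper", "middle", "lower"),
                                speeds = c(0.6, 0.8, 1.0, 1.2, 1.4),
                                bpm_base = 90, segment_s = 60, seed = 1,
                                rate = 100, ranges = default_joint_ranges()) {
  skeleton <- build_skeleton()
  dofs <- skeleton$dof
  classes <- expand.grid(speed = speeds, height = heights,
                         stringsAsFactors = FALSE)[, c("height", "speed")]
  alloc <- list( # shoulder amplitude, elbow amplitude, shoulder mean
    upper = c(sh = 50, el = 20, sh0 = 70),
    middle = c(sh = 15, el = 60, sh0 = 25),
    lower = c(sh = 35, el = 45, sh0 = 0)
  )
  nT_seg <- round(segment_s * rate)
  nT <- nrow(classes) * nT_seg
  times <- (seq_len(nT) - 1) / rate
  with_seed(seed, {
    A <- matrix(0, nT, length(dofs))
    for (k in seq_along(dofs)) A[, k] <- smooth_jitter(times, 1)
    for (i in seq_len(nrow(classes))) {
      hp <- alloc[[classes$height[i]]]
      f <- classes$speed[i] * bpm_base / 60 / 2  # full reach cycle frequency
      rows <- (i - 1L) * nT_seg + seq_len(nT_seg)
      tl <- times[rows] - times[rows[1]]
      ph <- stats::runif(1, 0, 2 * pi)
      wobble <- 1 + 0.02 * sin(2 * pi * 0.05 * tl + stats::runif(1, 0, 2 * pi))
      osc <- sin(2 * pi * f * tl + ph) * wobble
      side <- cos(2 * pi * f * tl + ph) * wobble  # lateral sweep, quadrature
      set_dof <- function(d, v) A[rows, match(d, dofs)] <<- v
      set_dof("LS_X", hp["sh0"] + hp["sh"] * osc)
      set_dof("RS_X", hp["sh0"] + hp["sh"] * -osc)
      set_dof("LS_Z", 25 + 20 * side)
      set_dof("RS_Z", -25 + 20 * side)
      set_dof("LE_X", 55 + hp["el"] * -osc)
      set_dof("RE_X", 55 + hp["el"] * osc)
      set_dof("T_Y", 8 * side)
    }
    A <- clip_to_ranges(A, dofs, ranges)
    stream <- angle_stream_tbl(times, A, dofs)
    protocol <- protocol_tbl(
      start_s = (seq_len(nrow(classes)) - 1) * segment_s,
      end_s = seq_len(nrow(classes)) * segment_s,
      label = sprintf("%s_%.1fx", classes$height, classes$speed)
    )
    list(stream = stream, protocol = protocol)
  })
}

gait_class_table <- function(speeds, widths, slopes) {
  dplyr::bind_rows(
    tibble::tibble(label = sprintf("speed_%.1fx", speeds),
                   speed = speeds, width = "regular", slope = 0),
    tibble::tibble(label = paste0("width_", widths),
                   speed = 1.0, width = widths, slope = 0),
    tibble::tibble(label = sprintf("slope_%+d", slopes),
                   speed = 1.0, width = "regular", slope = slopes)
  )
}

#' Treadmill gait protocol
#'
#' Periodic thigh/knee/arm-swing patterns with class-specific signatures:
#' cadence and stride amplitude grow with the speed multiplier; step-width
#' classes redistribute hip-abduction versus knee amplitude (with trunk roll
#' for sway); incline raises hip flexion and lowers knee amplitude, decline
#' the reverse, and declines are walked slightly faster. Left and right
#' limbs are half a cycle out of phase. Each class is one labeled segment.
#'
#' Classes sharing a nominal condition (regular width, 1.0x, 0 deg appears in
#' all three families, as in the study protocol) remain distinct classes:
#' each class carries a seeded "session style" — small amplitude, offset and
#' cadence idiosyncrasies of the kind a wearer shows between recording
#' sessions (`style_sd` scales them).
#'
#' @param speeds Speed multipliers (1.0x corresponds to 1.18 m/s).
#' @param widths Step-width classes.
#' @param slopes Treadmill slopes in degrees.
#' @param segment_s Seconds per class segment.
#' @param seed Integer seed.
#' @param rate Frame rate (Hz).
#' @param style_sd Relative sd of the per-class session-style amplitude
#'   multipliers (cadence jitter is style_sd/2, offsets 0.8 deg per unit).
#' @param ranges A `joint_ranges` tibble.
#' @return List with `stream`, `protocol`, and `classes` (the signature
#'   table).
#' @export
gait_protocol <- function(speeds = c(0.6, 0.8, 1.0, 1.2),
                          widths = c("narrow-", "narrow", "regular", "wide", "sway"),
                          slopes = c(-6L, -3L, 0L, 3L, 6L, 9L),
                          segment_s = 60, seed = 1, rate = 100,
                          style_sd = 0.015,
                          ranges = default_joint_ranges()) {
  skeleton <- build_skeleton()
  dofs <- skeleton$dof
  classes <- gait_class_table(speeds, slopes = slopes, widths = widths)
  # Step width is foremost a stance geometry: the feet track lines a fixed
  # distance apart, i.e. a static hip-abduction offset (abd0, degrees,
  # negative = crossing the midline), on top of which the classes
  # redistribute abduction swing vs knee amplitude; sway adds trunk roll.
  width_sig <- list( # hip factor, knee factor, abd offset, abd amp
    `narrow-` = c(hip = 1.00, knee = 1.15, abd0 = -3, abd = 2),
    narrow = c(hip = 1.00, knee = 1.08, abd0 = 0, abd = 3.5),
    regular = c(hip = 1.00, knee = 1.00, abd0 = 4, abd = 5),
    wide = c(hip = 1.02, knee = 0.95, abd0 = 10, abd = 10),
    sway = c(hip = 1.10, knee = 0.90, abd0 = 6, abd = 14)
  )
  f0 <- 0.9  # stride frequency at 1.0x, Hz
  nT_seg <- round(segment_s * rate)
  nT <- nrow(classes) * nT_seg
  times <- (seq_len(nT) - 1) / rate
  with_seed(seed, {
    A <- matrix(0, nT, length(dofs))
    for (k in seq_along(dofs)) A[, k] <- smooth_jitter(times, 0.8)
    for (i in seq_len(nrow(classes))) {
      cl <- classes[i, ]
      ws <- width_sig[[cl$width]]
      style <- function(n = 1) pmax(0.2, 1 + style_sd * stats::rnorm(n))
      doff <- function() 0.8 * stats::rnorm(1)
      f <- f0 * (0.5 + 0.5 * cl$speed) * (1 - 0.012 * cl$slope) *
        (1 + style_sd / 2 * stats::rnorm(1))
      amp_scale <- 0.6 + 0.4 * cl$speed
      hip_amp <- (30 + 0.5 * cl$slope) * amp_scale * ws["hip"] * style()
      hip_mean <- 5 + 0.8 * cl$slope + doff()
      knee_amp <- (28 - 0.7 * cl$slope) * amp_scale * ws["knee"] * style()
      knee_mean <- knee_amp + 2 + abs(doff())
      abd_amp <- ws["abd"] * style()
      abd_mean <- ws["abd0"] + doff() / 2
      roll_amp <- (if (cl$width == "sway") 8 else 2) * style()
      arm_amp <- 10 * amp_scale * style()
      # faster walking leans the trunk slightly forward
      trunk_mean <- 2 + 5 * (cl$speed - 1) + 0.3 * cl$slope + doff()
      rows <- (i - 1L) * nT_seg + seq_len(nT_seg)
      tl <- times[rows] - times[rows[1]]
      ph0 <- stats::runif(1, 0, 2 * pi)
      cyc <- function(lag, side = 0) sin(2 * pi * f * tl + ph0 + lag + side * pi)
      set_dof <- function(d, v) A[rows, match(d, dofs)] <<- v
      set_dof("LT_X", hip_mean + hip_amp * cyc(0))
      set_dof("RT_X", hip_mean + hip_amp * cyc(0, side = 1))
      set_dof("LK_X", knee_mean + knee_amp * cyc(0.35 * pi))
      set_dof("RK_X", knee_mean + knee_amp * cyc(0.35 * pi, side = 1))
      set_dof("LT_Z", -(abd_mean + abd_amp * pmax(0, cyc(pi / 2))))
      set_dof("RT_Z", abd_mean + abd_amp * pmax(0, cyc(pi / 2, side = 1)))
      set_dof("LB_Z", roll_amp * cyc(pi / 2))
      set_dof("LB_X", trunk_mean + 1.5 * sin(4 * pi * f * tl + ph0))
      set_dof("PV_X", 3 + 2 * sin(4 * pi * f * tl + 2 * ph0))
      set_dof("LS_X", arm_amp * cyc(0, side = 1))
      set_dof("RS_X", arm_amp * cyc(0))
      set_dof("LE_X", 15 + 0.5 * arm_amp * cyc(0.2 * pi, side = 1))
      set_dof("RE_X", 15 + 0.5 * arm_amp * cyc(0.2 * pi))
    }
    A <- clip_to_ranges(A, dofs, ranges)
    stream <- angle_stream_tbl(times, A, dofs)
    protocol <- protocol_tbl(
      start_s = (seq_len(nrow(classes)) - 1) * segment_s,
      end_s = seq_len(nrow(classes)) * segment_s,
      label = classes$label
    )
    list(stream = stream, protocol = protocol, classes = classes)
  })
}

#' Prepend and append synchronization squats
#'
#' Adds `n` deep squat cycles (knee/hip flexion peaks) before and after the
#' stream, the deliberate bursts both recording systems can see, and shifts
#' the protocol segment times accordingly.
#'
#' @param stream An angle-stream tibble.
#' @param protocol Optional protocol tibble to shift.
#' @param n Squats per burst (default 5).
#' @param cycle_s Duration of one squat.
#' @param rest_s Still margin between the burst and the core motion.
#' @return List with the augmented `stream` and shifted `protocol`.
#' @export
add_sync_squats <- function(stream, protocol = NULL, n = 5, cycle_s = 1.2,
                            rest_s = 1) {
  if (nrow(stream) == 0) stop("empty stream", call. = FALSE)
  if (n == 0) return(list(stream = stream, protocol = protocol))
  rate <- stream_rate(stream)
  dofs <- stream_dofs(stream)
  lead_s <- n * cycle_s + rest_s
  nB <- round(n * cycle_s * rate)
  tb <- (seq_len(nB) - 1) / rate
  phase <- (tb %% cycle_s) / cycle_s
  burst <- matrix(0, nB + round(rest_s * rate), length(dofs),
                  dimnames = list(NULL, dofs))
  kneecurve <- 110 * sin(pi * phase)
  burst[seq_len(nB), "LK_X"] <- kneecurve
  burst[seq_len(nB), "RK_X"] <- kneecurve
  burst[seq_len(nB), "LT_X"] <- 90 * sin(pi * phase)
  burst[seq_len(nB), "RT_X"] <- 90 * sin(pi * phase)
  burst[seq_len(nB), "LB_X"] <- 20 * sin(pi * phase)
  A <- as.matrix(stream[, dofs])
  A_full <- rbind(burst, A, burst)
  nT <- nrow(A_full)
  times <- (seq_len(nT) - 1) / rate
  out <- angle_stream_tbl(times, A_full, dofs)
  if (!is.null(protocol)) {
    protocol <- dplyr::mutate(protocol,
                              start_s = .data$start_s + lead_s,
                              end_s = .data$end_s + lead_s)
  }
  list(stream = out, protocol = protocol)
}
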