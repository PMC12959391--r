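# Stream conditioning: linear resampling to the 100 Hz reference clock,
# zero-phase Butterworth filtering of reference angles, squat-peak
# synchronization of the sensor and angle clocks, 3:1:1 splitting, and the
# summary statistics used throughout (min-max normalization, summed
# angle-change rate).

#' Resample a stream by linear interpolation
#'
#' Interpolates every numeric column onto a uniform grid at `target_rate`
#' spanning the input's time range. Endpoint values are preserved and
#' outputs never leave the local input envelope (linear interpolation).
#'
#' @param stream Tibble with `time_s` plus numeric columns.
#' @param target_rate Target rate in Hz (default 100).
#' @return Resampled tibble (same class as the input).
#' @export
resample_linear <- function(stream, target_rate = 100) {
  t_in <- stream$time_s
  if (length(t_in) < 2) stop("need at least 2 frames", call. = FALSE)
  if (any(diff(t_in) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  cols <- setdiff(names(stream), c("time_s", "label", "split"))
  ts <- t_in[1] + seq(0, floor((t_in[length(t_in)] - t_in[1]) * target_rate)) /
    target_rate
  idx <- pmin(findInterval(ts, t_in), length(t_in) - 1L)
  frac <- (ts - t_in[idx]) / (t_in[idx + 1L] - t_in[idx])
  M <- as.matrix(stream[, cols])
  out <- M[idx, , drop = FALSE] * (1 - frac) + M[idx + 1L, , drop = FALSE] * frac
  res <- dplyr::bind_cols(tibble::tibble(time_s = ts),
                          tibble::as_tibble(as.data.frame(out)))
  class(res) <- class(stream)
  res
}

#' Zero-phase Butterworth low-pass of reference angles
#'
#' Fourth-order Butterworth low-pass (default 10 Hz cutoff) applied
#' forward-backward (zero phase) to every DoF column, the standard
#' treatment for suppressing marker vibration in optical reference
#' kinematics.
#'
#' @param stream Angle-stream tibble at a uniform rate.
#' @param order Filter order (default 4).
#' @param cutoff Cutoff frequency in Hz (default 10).
#' @return Filtered tibble.
#' @export
lowpass_reference <- function(stream, order = 4, cutoff = 10) {
  rate <- stream_rate(stream)
  if (rate <= 2 * cutoff) {
    stop("sampling rate ", round(rate, 2), " Hz too low for a ", cutoff,
         " Hz cutoff", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  cols <- setdiff(names(stream), c("time_s", "label", "split"))
  n <- nrow(stream)
  # odd-reflection padding suppresses the forward-backward edge transients
  # (the plain filter starts from zero initial conditions)
  n_pad <- min(n - 1L, 10L * ceiling(rate / cutoff))
  out <- stream
  for (cn in cols) {
    x <- stream[[cn]]
    xp <- c(2 * x[1] - x[(n_pad + 1L):2L],
            x,
            2 * x[n] - x[(n - 1L):(n - n_pad)])
    y <- as.numeric(signal::filtfilt(bf, xp))
    out[[cn]] <- y[n_pad + seq_len(n)]
  }
  out
}

# Sub-sample peak localization: quadratic fit through the peak and its two
# neighbours.
refine_peak_times <- function(x, t, peak_idx) {
  vapply(peak_idx, function(i) {
    if (i <= 1L || i >= length(x)) return(t[i])
    y0 <- x[i - 1L]; y1 <- x[i]; y2 <- x[i + 1L]
    den <- y0 - 2 * y1 + y2
    if (abs(den) < 1e-12) return(t[i])
    delta <- 0.5 * (y0 - y2) / den
    t[i] + delta * (t[i + 1L] - t[i])
  }, 1)
}

squat_peak_trains <- function(x, t, n, prominence) {
  # peakpat admits flat crests (exactly tied samples at a sinusoid maximum)
  pk <- pracma::findpeaks(x, minpeakheight = prominence,
                          peakpat = "[+]{1,}[0]*[-]{1,}",
                          minpeakdistance = max(1L, round(0.4 * length(t) /
                                                            (t[length(t)] - t[1]))))
  if (is.null(pk) || nrow(pk) < 2 * n) {
    stop("synchronization failed: found ", if (is.null(pk)) 0 else nrow(pk),
         " squat peaks, need ", 2 * n, call. = FALSE)
  }
  idx <- sort(pk[, 2])
  tt <- refine_peak_times(x, t, idx)
  list(first = tt[seq_len(n)], last = tt[length(tt) - n:1 + 1])
}

# Lag of a sensor channel against a reference burst by windowed
# cross-covariance (polarity-insensitive), with parabolic sub-sample
# refinement. Both series are interpolated onto a common grid.
burst_xcorr_lag <- function(ref_t, ref_x, sens_t, sens_x, center,
                            half_window, max_lag, rate = 100) {
  grid_r <- seq(center - half_window, center + half_window, by = 1 / rate)
  grid_s <- seq(center - half_window - max_lag, center + half_window + max_lag,
                by = 1 / rate)
  r <- stats::approx(ref_t, ref_x, xout = grid_r, rule = 2)$y
  s <- stats::approx(sens_t, sens_x, xout = grid_s, rule = 2)$y
  r <- r - mean(r); s <- s - mean(s)
  # full cross-covariance: conv[n] = sum_j r[j] * s[j + (n - m)], m = len(r);
  # the valid slice n = m..len(s) spans sensor-minus-reference shifts of
  # -max_lag .. +max_lag on the common grid
  xc <- stats::convolve(s, rev(r), type = "open")
  xc <- xc[length(r):length(s)]
  shifts <- seq(-max_lag, max_lag, by = 1 / rate)
  stopifnot(length(xc) == length(shifts))
  i <- which.max(abs(xc))
  score <- abs(xc[i]) / (sqrt(sum(r^2)) *
                           sqrt(sum(s^2) * length(r) / length(s)) + 1e-12)
  shift <- shifts[i]
  if (i > 1 && i < length(xc)) {
    y0 <- abs(xc[i - 1]); y1 <- abs(xc[i]); y2 <- abs(xc[i + 1])
    den <- y0 - 2 * y1 + y2
    if (abs(den) > 1e-12) shift <- shift + 0.5 * (y0 - y2) / den / rate
  }
  # the sensor shows the burst at t_s = t_ref + shift, so lag = t_ref - t_s
  list(lag = -shift, score = score)
}

#' Synchronize sensor and angle streams by squat peaks
#'
#' Automated counterpart of visually matching the deliberate squat bursts
#' recorded at the start and end of a session: detects the knee-angle peak
#' trains in the reference stream and the corresponding capacitance peak
#' trains in a knee-associated channel, estimates the clock offset and
#' linear clock scale from the first and last trains, and resamples the
#' sensor stream onto the reference clock.
#'
#' @param sensors A `sensor_stream` tibble.
#' @param angles An angle-stream tibble containing the squats.
#' @param design Optional `suit_design` used to pick the knee channel
#'   (first sensor whose joint is LK/RK); otherwise `knee_channel` is
#'   required.
#' @param knee_channel Channel column name, e.g. `"ch05"`.
#' @param n Squats per burst (default 5).
#' @param prominence Knee-angle peak threshold in degrees (default 60).
#' @param max_lag_s Largest clock offset searched (s).
#' @return Tibble at the reference rate: `time_s`, sensor channels, DoF
#'   columns; attributes `offset_s` and `clock_scale` hold the estimated
#'   alignment (`time_angle = clock_scale * time_sensor + offset_s`).
#' @export
synchronize_streams <- function(sensors, angles, design = NULL,
                                knee_channel = NULL, n = 5, prominence = 60,
                                max_lag_s = 10) {
  knee_dof <- if ("LK_X" %in% names(angles)) "LK_X" else "RK_X"
  tr_a <- squat_peak_trains(angles[[knee_dof]], angles$time_s, n, prominence)
  if (is.null(knee_channel)) {
    if (is.null(design)) stop("need design or knee_channel", call. = FALSE)
    ch <- design$sensors$channel[design$sensors$joint %in% c("LK", "RK")]
    if (length(ch) == 0) stop("design has no knee sensor", call. = FALSE)
    knee_channel <- sprintf("ch%02d", sort(ch))
  }
  # The knee-angle squat bursts are the reference templates; each candidate
  # knee channel is cross-correlated against them (|covariance|, so a
  # buckling-side channel whose capacitance dips during flexion works too),
  # and the channel with the strongest normalized correlation wins.
  a_first <- mean(tr_a$first); a_last <- mean(tr_a$last)
  hw <- (max(tr_a$first) - min(tr_a$first)) / 2 + 2
  rate_a <- stream_rate(angles)
  best <- NULL
  for (cn in knee_channel) {
    m1 <- burst_xcorr_lag(angles$time_s, angles[[knee_dof]],
                          sensors$time_s, sensors[[cn]],
                          center = a_first, half_window = hw,
                          max_lag = max_lag_s, rate = rate_a)
    m2 <- burst_xcorr_lag(angles$time_s, angles[[knee_dof]],
                          sensors$time_s, sensors[[cn]],
                          center = a_last, half_window = hw,
                          max_lag = max_lag_s, rate = rate_a)
    score <- min(m1$score, m2$score)
    if (is.null(best) || score > best$score) {
      best <- list(channel = cn, score = score, lag1 = m1$lag, lag2 = m2$lag)
    }
  }
  if (is.null(best) || best$score < 0.4) {
    stop("synchronization failed: best squat-burst correlation ",
         round(best$score %||% 0, 3), " on channel ",
         best$channel %||% "<none>",
         " (need >= 0.4); are the squat bursts present in both streams?",
         call. = FALSE)
  }
  # burst k appears in the sensor clock at t_s = t_a(k) - lag_k;
  # t_a = scale * t_s + offset through both bursts
  s_first <- a_first - best$lag1
  s_last <- a_last - best$lag2
  scale <- (a_last - a_first) / (s_last - s_first)
  offset <- a_first - scale * s_first
  mapped <- sensors
  mapped$time_s <- scale * sensors$time_s + offset
  rate <- stream_rate(angles)
  t0 <- max(angles$time_s[1], mapped$time_s[1])
  t1 <- min(angles$time_s[nrow(angles)], mapped$time_s[nrow(mapped)])
  grid <- angles$time_s[angles$time_s >= t0 & angles$time_s <= t1]
  interp_onto <- function(stream, grid) {
    t_in <- stream$time_s
    cols <- setdiff(names(stream), "time_s")
    idx <- pmin(pmax(findInterval(grid, t_in), 1L), length(t_in) - 1L)
    frac <- (grid - t_in[idx]) / (t_in[idx + 1L] - t_in[idx])
    M <- as.matrix(stream[, cols])
    out <- M[idx, , drop = FALSE] * (1 - frac) + M[idx + 1L, , drop = FALSE] * frac
    tibble::as_tibble(as.data.frame(out))
  }
  out <- dplyr::bind_cols(
    tibble::tibble(time_s = grid),
    interp_onto(mapped, grid),
    angles[match(grid, angles$time_s), setdiff(names(angles), "time_s")]
  )
  attr(out, "offset_s") <- offset
  attr(out, "clock_scale") <- scale
  out
}

#' Split a dataset 3:1:1
#'
#' Random mode permutes frames with the given seed; sequential mode takes
#' contiguous blocks in time order — per labeled segment when a `label`
#' column is present (each class's own timeline is split 3:1:1, the
#' discipline used for sequence classification), globally otherwise.
#' Remainder frames go to train.
#'
#' @param data Tibble of frames.
#' @param mode `"random"` or `"sequential"`.
#' @param ratio Train/validation/test proportions (default 3:1:1).
#' @param seed Seed for random mode.
#' @return `data` with a `split` factor column (`train`/`val`/`test`).
#' @export
split_dataset <- function(data, mode = c("random", "sequential"),
                          ratio = c(3, 1, 1), seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(data)
  if (n < 5) stop("need at least 5 frames to split 3:1:1", call. = FALSE)
  assign_block <- function(n) {
    nv <- floor(n * ratio[2] / sum(ratio))
    nt <- floor(n * ratio[3] / sum(ratio))
    c(rep("train", n - nv - nt), rep("val", nv), rep("test", nt))
  }
  if (mode == "random") {
    split <- with_seed(seed, sample(assign_block(n)))
  } else if ("label" %in% names(data) && any(!is.na(data$label))) {
    runs <- rle(paste0(data$label, ""))
    split <- unlist(lapply(runs$lengths, assign_block), use.names = FALSE)
  } else {
    split <- assign_block(n)
  }
  data$split <- factor(split, levels = c("train", "val", "test"))
  data
}

#' Min-max normalization to \[0, 1\]
#'
#' `(x - min(x)) / (max(x) - min(x))`, the normalization used for
#' whole-day sensor traces.
#'
#' @param x Numeric vector.
#' @return Normalized vector with min 0 and max 1.
#' @export
minmax_normalize <- function(x) {
  lo <- min(x); hi <- max(x)
  if (!(hi > lo)) stop("constant series cannot be min-max normalized", call. = FALSE)
  (x - lo) / (hi - lo)
}

#' Summed angle-change rate
#'
#' The motion-complexity statistic: per frame, the total absolute angular
#' change of all DoFs over one 10 ms step, in degrees per 10 ms (at the
#' 100 Hz reference rate one frame step is exactly 10 ms).
#'
#' @param stream Angle-stream tibble at 100 Hz.
#' @return Tibble `time_s`, `rate_deg_per_10ms`; the stream-level statistic
#'   is its mean, also attached as attribute `mean_rate`.
#' @export
summed_angle_change_rate <- function(stream) {
  dofs <- stream_dofs(stream)
  A <- as.matrix(stream[, dofs])
  d <- rowSums(abs(A[-1, , drop = FALSE] - A[-nrow(A), , drop = FALSE]))
  out <- tibble::tibble(time_s = stream$time_s[-1], rate_deg_per_10ms = d)
  attr(out, "mean_rate") <- mean(d)
  out
}

#' Build an aligned sensor/angle dataset
#'
#' Convenience pipeline step: simulate (or take) a sensor stream, resample
#' it to the reference rate, and join it with the ground-truth angles and
#' optional per-frame labels.
#'
#' @param sensors A `sensor_stream`.
#' @param angles An angle-stream tibble (reference clock).
#' @param protocol Optional protocol tibble for per-frame labels.
#' @return Tibble: `time_s`, channels, DoF columns, optional `label`.
#' @export
align_streams <- function(sensors, angles, protocol = NULL) {
  rate <- stream_rate(angles)
  s100 <- resample_linear(sensors, target_rate = rate)
  nT <- min(nrow(s100), nrow(angles))
  out <- dplyr::bind_cols(
    angles[seq_len(nT), "time_s"],
    s100[seq_len(nT), stream_channels(s100)],
    angles[seq_len(nT), setdiff(names(angles), "time_s")]
  )
  if (!is.null(protocol)) out$label <- protocol_labels(out$time_s, protocol)
  out
}
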