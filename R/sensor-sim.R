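# Forward model from posed skin geometry to 40 Hz capacitance streams.
# Each channel measures the strain of its fixed surface path; capacitance
# follows a linear gauge law around a 100 pF base (the textile units are
# monotone with low hysteresis, so no hysteresis is modelled), plus a
# parasitic trace offset, a spatially propagating additive drift, and
# seeded white measurement noise.

#' Sensor electrical parameters
#'
#' Capacitance model `C(s, t) = c_base * (1 + gauge * max(s, 0)) + c_trace +
#' drift(t) + noise`, strain `s` clamped below at `strain_floor` (slack
#' fabric buckles instead of compressing).
#'
#' In a worn suit the sensors are not at rest: the form-fitting base garment
#' holds them under a mounting pre-tension (`pre_strain`, default 15%
#' elongation), so skin contraction under a sensor reads as a capacitance
#' drop rather than vanishing into the rectified zero-strain regime. Stream
#' simulation applies the gauge law to
#' `max(pre_strain + max(s, strain_floor), 0)`.
#'
#' @param c_base Zero-strain capacitance (pF); default 100, matching the
#'   measured ~100 pF base of the textile units.
#' @param gauge Dimensionless gain of the linear gauge law (> 0:
#'   capacitance increases with strain).
#' @param c_trace Parasitic offset from the conductive traces (pF).
#' @param noise_sd Measurement noise sd (pF).
#' @param seed Integer seed; fans out to independent per-channel substreams.
#' @param strain_floor Lower clamp on the skin-path strain (dimensionless).
#' @param pre_strain Garment mounting pre-tension (dimensionless).
#' @return List of class `sensor_params`.
#' @export
sensor_params <- function(c_base = 100, gauge = 0.8, c_trace = 5,
                          noise_sd = 0.05, seed = 1, strain_floor = -0.05,
                          pre_strain = 0.15) {
  stopifnot(c_base > 0, gauge > 0, noise_sd >= 0, pre_strain >= 0)
  structure(list(c_base = c_base, gauge = gauge, c_trace = c_trace,
                 noise_sd = noise_sd, seed = seed,
                 strain_floor = strain_floor, pre_strain = pre_strain),
            class = "sensor_params")
}

#' Spatially propagating drift model
#'
#' Additive capacitance drift that starts at seed regions (default the
#' armpits and knees, where sweating begins) and spreads across the skin at
#' a fixed geodesic speed. Each channel's onset is delayed by its geodesic
#' distance from the nearest seed region; after onset the drift rises as a
#' saturating exponential to `max_drift`. Zero at t = 0 and non-decreasing
#' in time.
#'
#' @param seed_regions Region names among `"left_armpit"`, `"right_armpit"`,
#'   `"left_knee"`, `"right_knee"`.
#' @param onset_time Global delay before any drift (s).
#' @param propagation_speed Spreading speed over the skin (m/s).
#' @param max_drift Saturation amplitude (pF).
#' @param tau Rise time constant (s).
#' @return List of class `drift_model`.
#' @export
drift_model <- function(seed_regions = c("left_armpit", "right_armpit",
                                         "left_knee", "right_knee"),
                        onset_time = 60, propagation_speed = 0.002,
                        max_drift = 8, tau = 180) {
  known <- c("left_armpit", "right_armpit", "left_knee", "right_knee")
  bad <- setdiff(seed_regions, known)
  if (length(bad) > 0) {
    stop("unknown drift seed region(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(onset_time >= 0, propagation_speed > 0, max_drift >= 0, tau > 0)
  structure(list(seed_regions = seed_regions, onset_time = onset_time,
                 propagation_speed = propagation_speed,
                 max_drift = max_drift, tau = tau),
            class = "drift_model")
}

drift_region_anchor <- function(skeleton, region) {
  pos <- skeleton$rest_pos
  switch(region,
    left_armpit = pos["LS", ] + c(0.05 * sign(pos["LS", 1]), -0.07, 0),
    right_armpit = pos["RS", ] + c(0.05 * sign(pos["RS", 1]), -0.07, 0),
    left_knee = pos["LK", ],
    right_knee = pos["RK", ]
  )
}

#' Per-channel drift field for a suit design
#'
#' Resolves the drift model's seed regions to skin locations and assigns
#' each channel an onset delay proportional to its geodesic distance from
#' the nearest seed region.
#'
#' @param body The body.
#' @param design A `suit_design`.
#' @param model A [drift_model()].
#' @return Object of class `drift_field`: tibble `onsets` (channel,
#'   distance, onset_s) plus the model; callable via [drift_values()].
#' @export
build_drift_field <- function(body, design, model = drift_model()) {
  geo <- build_geodesic_graph(body$mesh)
  seeds <- vapply(model$seed_regions, function(r) {
    nearest_vertex(body$mesh$vertices,
                   drift_region_anchor(body$skeleton, r))
  }, 1L)
  D <- igraph::distances(geo$g, v = seeds, weights = geo$weights)
  centers <- design$sensors$center_vertex
  dist <- apply(D[, centers, drop = FALSE], 2, min)
  onsets <- tibble::tibble(
    channel = design$sensors$channel,
    distance = unname(dist),
    onset_s = model$onset_time + unname(dist) / model$propagation_speed
  )
  structure(list(onsets = onsets, model = model), class = "drift_field")
}

#' Drift values
#'
#' @param field A `drift_field`.
#' @param t Time vector (s).
#' @param channels Channel ids (default all in the field).
#' @return Matrix `length(t)` x `length(channels)` of drift offsets (pF).
#' @export
drift_values <- function(field, t, channels = field$onsets$channel) {
  m <- field$model
  idx <- match(channels, field$onsets$channel)
  onset <- field$onsets$onset_s[idx]
  out <- matrix(0, length(t), length(channels))
  for (k in seq_along(channels)) {
    dt <- pmax(0, t - onset[k])
    out[, k] <- m$max_drift * (1 - exp(-dt / m$tau))
  }
  out
}

#' Strain of designed sensors on a posed mesh
#'
#' Relative elongation of each sensor's fixed surface path, measured on
#' posed vertex positions and clamped below at the slack floor.
#'
#' @param design A `suit_design`.
#' @param posed_vertices N x 3 posed vertex matrix (e.g. from
#'   [skin_vertices()]); defaults must match the design's mesh.
#' @param strain_floor Lower clamp (default -0.05).
#' @return Numeric vector of strains, one per channel.
#' @export
sensor_strain <- function(design, posed_vertices, strain_floor = -0.05) {
  vapply(seq_len(nrow(design$sensors)), function(i) {
    comp <- design$sensors$path_comp[[i]]
    pts <- posed_vertices[comp[, 1], , drop = FALSE] * comp[, 3] +
      posed_vertices[comp[, 2], , drop = FALSE] * comp[, 4]
    L <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2)))
    L0 <- design$sensors$rest_length[i]
    if (L0 <= 0) stop("degenerate rest length", call. = FALSE)
    max((L - L0) / L0, strain_floor)
  }, 1)
}

#' Capacitance response
#'
#' The gauge law: `C = c_base * (1 + gauge * max(s, 0)) + c_trace + drift +
#' eps`. Strictly increasing in strain for s >= 0 at zero noise.
#'
#' @param s Strain(s).
#' @param t Time(s), seconds (recycled against `s`).
#' @param params A [sensor_params()].
#' @param field Optional `drift_field`.
#' @param channel Channel id (for the drift lookup).
#' @param eps Optional explicit noise values (pF); default 0. Streams draw
#'   their noise from per-channel seeded substreams in [simulate_stream()].
#' @return Capacitance(s) in pF.
#' @export
capacitance_response <- function(s, t = 0, params = sensor_params(),
                                 field = NULL, channel = 0L, eps = 0) {
  if (any(s < params$strain_floor - 1e-12)) {
    stop("strain below the clamp floor ", params$strain_floor, call. = FALSE)
  }
  drift <- if (is.null(field)) 0 else
    drift_values(field, rep_len(t, length(s)), channels = channel)[, 1]
  params$c_base * (1 + params$gauge * pmax(s, 0)) + params$c_trace +
    drift + eps
}

#' Simulate the 40 Hz sensor stream
#'
#' Samples the angle stream at the sensor rate (linear interpolation),
#' poses the skin, measures every sensor path's strain, and applies the
#' capacitance model with optional drift and per-channel seeded noise.
#' Channels are ordered by channel id (`ch00`, `ch01`, ...). Reproducible
#' for a fixed seed.
#'
#' @param body The body.
#' @param design A `suit_design`.
#' @param stream An angle-stream tibble (100 Hz ground truth).
#' @param params A [sensor_params()].
#' @param field Optional `drift_field`.
#' @param rate Sensor sampling rate (Hz), default 40.
#' @return A tibble of class `sensor_stream`: `time_s` plus one `chNN`
#'   column per sensor (pF).
#' @export
simulate_stream <- function(body, design, stream, params = sensor_params(),
                            field = NULL, rate = 40) {
  if (nrow(design$sensors) == 0 || nrow(stream) < 2) {
    stop("empty design or angle stream", call. = FALSE)
  }
  dofs <- stream_dofs(stream, body$skeleton)
  A <- as.matrix(stream[, dofs])
  t_in <- stream$time_s
  ts <- seq(t_in[1], t_in[length(t_in)], by = 1 / rate)
  idx <- pmin(findInterval(ts, t_in), length(t_in) - 1L)
  frac <- (ts - t_in[idx]) / (t_in[idx + 1L] - t_in[idx])
  A40 <- A[idx, , drop = FALSE] * (1 - frac) + A[idx + 1L, , drop = FALSE] * frac
  # order columns into the skeleton's full DoF layout
  full <- matrix(0, nrow(A40), length(body$skeleton$dof),
                 dimnames = list(NULL, body$skeleton$dof))
  full[, dofs] <- A40
  sens <- design$sensors[order(design$sensors$channel), ]
  pts <- list(pos = do.call(rbind, sens$path_pos),
              w = do.call(rbind, sens$path_w))
  ks <- vapply(sens$path_pos, nrow, 1L)
  offs <- cumsum(c(0L, ks[-length(ks)]))
  paths <- purrr::map2(offs, ks, function(o, k) o + seq_len(k))
  B <- path_basis(pts, body$skeleton)
  L <- path_lengths_batch(B, body$skeleton, full, paths)
  L0 <- sens$rest_length
  S <- pmax(sweep(sweep(L, 2, L0), 2, L0, `/`), params$strain_floor)
  S_eff <- pmax(S + params$pre_strain, 0)  # gauge strain under mounting tension
  C <- params$c_base * (1 + params$gauge * S_eff) + params$c_trace
  if (!is.null(field)) {
    C <- C + drift_values(field, ts, channels = sens$channel)
  }
  if (params$noise_sd > 0) {
    for (k in seq_len(ncol(C))) {
      C[, k] <- C[, k] + with_seed(
        substream_seed(params$seed, sens$channel[k]),
        stats::rnorm(nrow(C), 0, params$noise_sd)
      )
    }
  }
  colnames(C) <- sprintf("ch%02d", sens$channel)
  out <- dplyr::bind_cols(tibble::tibble(time_s = ts),
                          tibble::as_tibble(as.data.frame(C)))
  class(out) <- c("sensor_stream", class(out))
  out
}
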