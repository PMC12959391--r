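# Drift-injection study: repeat the multijoint routine with standing pauses
# while the drift field is active throughout, then recover each channel's
# slow baseline and onset time and check the spatial onset ordering.

#' Run the drift-injection experiment
#'
#' Concatenates `repetitions` of a multijoint routine with standing pauses
#' in between (the wearer rests between rounds), simulates the sensors with
#' the drift field active over the whole timeline, and estimates each
#' channel's drift baseline (via [drift_baseline()]) and onset time — the
#' first time the baseline rises 5% of `max_drift` above its start.
#'
#' @param body The body.
#' @param design A `suit_design`.
#' @param routine An angle-stream tibble for one activity round (default: a
#'   4-minute multijoint routine).
#' @param repetitions Activity rounds (default 3).
#' @param pause_s Standing pause between rounds (default 240 s).
#' @param drift A [drift_model()].
#' @param params A [sensor_params()].
#' @param baseline_window Savitzky-Golay window (frames at the reference
#'   rate).
#' @param seed Seed for the routine generator when `routine` is NULL.
#' @return List: `dataset` (aligned tibble), `report` (class
#'   `drift_report`: `onsets` tibble with estimated onset per channel,
#'   `baselines` tibble), `field` (the drift field used).
#' @export
drift_experiment <- function(body, design, routine = NULL, repetitions = 3,
                             pause_s = 240, drift = drift_model(),
                             params = sensor_params(),
                             baseline_window = 18000, seed = 1) {
  stopifnot(repetitions >= 1, pause_s >= 0)
  if (is.null(routine)) {
    routine <- multijoint_routine(duration_s = 240, seed = seed)
  }
  rate <- stream_rate(routine)
  dofs <- stream_dofs(routine)
  A <- as.matrix(routine[, dofs])
  pauseA <- matrix(0, round(pause_s * rate), ncol(A))
  blocks <- list()
  for (r in seq_len(repetitions)) {
    blocks[[length(blocks) + 1L]] <- A
    if (r < repetitions) blocks[[length(blocks) + 1L]] <- pauseA
  }
  full <- do.call(rbind, blocks)
  times <- (seq_len(nrow(full)) - 1) / rate
  stream <- angle_stream_tbl(times, full, dofs)
  field <- build_drift_field(body, design, drift)
  sensors <- simulate_stream(body, design, stream, params = params,
                             field = field)
  dataset <- align_streams(sensors, stream)
  base <- drift_baseline(dataset[, c("time_s", stream_channels(dataset))],
                         window = baseline_window)
  chs <- stream_channels(dataset)
  onset_est <- vapply(chs, function(cn) {
    b <- base[[cn]] - base[[cn]][1]
    thr <- 0.05 * drift$max_drift
    i <- which(b > thr)[1]
    if (is.na(i) || drift$max_drift == 0) NA_real_ else base$time_s[i]
  }, 1)
  onsets <- tibble::tibble(
    channel = as.integer(sub("^ch", "", chs)),
    onset_est_s = unname(onset_est)
  )
  onsets <- dplyr::left_join(onsets, field$onsets, by = "channel")
  report <- structure(list(onsets = onsets, baselines = base,
                           max_drift = drift$max_drift),
                      class = "drift_report")
  list(dataset = dataset, report = report, field = field)
}

#' @export
print.drift_report <- function(x, ...) {
  cat("<drift_report> ", nrow(x$onsets), " channels, ",
      sum(!is.na(x$onsets$onset_est_s)), " with detected onsets\n", sep = "")
  invisible(x)
}

#' @rdname tidy.calib_report
#' @method tidy drift_report
#' @export
tidy.drift_report <- function(x, ...) x$onsets
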