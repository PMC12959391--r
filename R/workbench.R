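# Experiment orchestration: one-call presets chaining body construction,
# suit design, motion generation, sensor simulation, preprocessing, model
# training and evaluation, with a single seed governing the whole run and a
# JSON manifest of every metric.

#' Run a preset end-to-end experiment
#'
#' Chains design -> simulate -> preprocess -> train -> evaluate for one of
#' the study protocols. One seed governs generation, simulation noise,
#' splitting and training. Results are returned as a report bundle and,
#' when `out_dir` is given, written as `metrics.json` plus a manifest.
#'
#' Presets:
#' \describe{
#'   \item{`single_joint`}{11-joint sweep protocol (~387 s), MLP
#'     calibration, random 3:1:1 split; reports the overall mean MAE.}
#'   \item{`multijoint`}{4-minute calisthenics-like routine at a mean
#'     summed angle-change rate of 15.9 deg/10 ms, same pipeline.}
#'   \item{`gait_widths`, `gait_slopes`, `gait_speeds`, `gait_all`}{Gait
#'     classes of one family (or all 15), LSTM classification with a
#'     sequential per-class 3:1:1 split; reports test accuracy.}
#'   \item{`pick_place`}{15 height x speed reach classes, LSTM pipeline.}
#'   \item{`drift`}{Repeat-routine drift injection with baseline recovery
#'     and mitigated recalibration.}
#' }
#'
#' @param preset Preset name.
#' @param seed Master seed.
#' @param body Optional prebuilt body (built from `body_config()` if NULL).
#' @param design Optional prebuilt `suit_design` (designed if NULL).
#' @param segment_s Per-class segment length for classification presets.
#' @param iterations Optional override of training iterations.
#' @param noise_sd Sensor noise (pF).
#' @param out_dir Optional output directory for metrics and manifest.
#' @return A list of class `experiment_report`: `preset`, `seed`, `metrics`
#'   (one-row tibble), plus the fitted model and evaluation objects.
#' @export
run_experiment <- function(preset = c("single_joint", "multijoint",
                                      "gait_widths", "gait_slopes",
                                      "gait_speeds", "gait_all",
                                      "pick_place", "drift"),
                           seed = 1, body = NULL, design = NULL,
                           segment_s = 60, iterations = NULL,
                           noise_sd = 0.05, out_dir = NULL) {
  preset <- match.arg(preset)
  body <- body %||% build_capsule_body()
  design <- design %||% design_suit(body)
  params <- sensor_params(noise_sd = noise_sd, seed = seed)
  out <- switch(
    preset,
    single_joint = {
      gen <- single_joint_protocol(seed = seed)
      run_calibration_experiment(body, design, gen$stream, params,
                                 seed = seed, iterations = iterations)
    },
    multijoint = {
      stream <- multijoint_routine(duration_s = 240, target_rate = 15.9,
                                   seed = seed)
      run_calibration_experiment(body, design, stream, params,
                                 seed = seed, iterations = iterations)
    },
    gait_widths = run_gait_experiment(body, design, params, seed, segment_s,
                                      iterations, speeds = numeric(0),
                                      slopes = integer(0)),
    gait_slopes = run_gait_experiment(body, design, params, seed, segment_s,
                                      iterations, speeds = numeric(0),
                                      widths = character(0)),
    gait_speeds = run_gait_experiment(body, design, params, seed, segment_s,
                                      iterations, widths = character(0),
                                      slopes = integer(0)),
    gait_all = run_gait_experiment(body, design, params, seed, segment_s,
                                   iterations),
    pick_place = {
      gen <- pick_place_protocol(segment_s = segment_s, seed = seed)
      run_classification_experiment(body, design, gen, params, seed,
                                    iterations)
    },
    drift = {
      de <- drift_experiment(body, design, seed = seed, params = params)
      dat <- split_dataset(de$dataset, mode = "random", seed = seed)
      cfg <- regressor_config(seed = seed,
                              iterations = iterations %||% 10000)
      model <- train_angle_regressor(dat, cfg)
      rep <- evaluate_regressor(model, dat)
      list(metrics = tibble::tibble(
             overall_mae_deg = rep$overall_mae_deg,
             channels_with_onset = sum(!is.na(de$report$onsets$onset_est_s))),
           model = model, evaluation = rep, drift_report = de$report)
    }
  )
  out$preset <- preset
  out$seed <- seed
  out$design_status <- design$status
  out$n_sensors <- nrow(design$sensors)
  class(out) <- "experiment_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(preset = preset, seed = seed,
           n_sensors = out$n_sensors,
           metrics = as.list(out$metrics)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

run_calibration_experiment <- function(body, design, stream, params, seed,
                                       iterations = NULL) {
  sensors <- simulate_stream(body, design, stream, params = params)
  dat <- align_streams(sensors, stream)
  dat <- split_dataset(dat, mode = "random", seed = seed)
  cfg <- regressor_config(seed = seed, iterations = iterations %||% 10000)
  model <- train_angle_regressor(dat, cfg)
  rep <- evaluate_regressor(model, dat)
  rate <- attr(summed_angle_change_rate(stream), "mean_rate")
  list(metrics = tibble::tibble(overall_mae_deg = rep$overall_mae_deg,
                                mean_rate_deg_10ms = rate,
                                n_frames = nrow(dat)),
       model = model, evaluation = rep, dataset = dat)
}

run_gait_experiment <- function(body, design, params, seed, segment_s,
                                iterations = NULL,
                                speeds = c(0.6, 0.8, 1.0, 1.2),
                                widths = c("narrow-", "narrow", "regular",
                                           "wide", "sway"),
                                slopes = c(-6L, -3L, 0L, 3L, 6L, 9L)) {
  gen <- gait_protocol(speeds = speeds, widths = widths, slopes = slopes,
                       segment_s = segment_s, seed = seed)
  run_classification_experiment(body, design, gen, params, seed, iterations)
}

run_classification_experiment <- function(body, design, gen, params, seed,
                                          iterations = NULL) {
  sensors <- simulate_stream(body, design, gen$stream, params = params)
  dat <- align_streams(sensors, gen$stream, protocol = gen$protocol)
  dat <- split_dataset(dat, mode = "sequential")
  cfg <- classifier_config(seed = seed, iterations = iterations %||% 1000)
  model <- train_motion_classifier(dat, cfg)
  rep <- evaluate_classifier(model, dat)
  list(metrics = dplyr::bind_cols(glance(rep)),
       model = model, evaluation = rep, dataset = dat)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> preset=", x$preset, " seed=", x$seed,
      " sensors=", x$n_sensors, "\n", sep = "")
  print(x$metrics)
  invisible(x)
}
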