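# Sensor-to-angle calibration: a 5 x 100 ReLU multilayer perceptron mapping
# standardized capacitance channels to joint angles in degrees, trained with
# mean-squared error and Adam (lr 1e-3, epsilon 1e-4, batch 64, 10,000
# mini-batch iterations), keeping the best-on-validation snapshot; plus the
# slow Savitzky-Golay drift baseline.

#' Regressor configuration
#'
#' Defaults mirror the study pipeline: five fully connected hidden layers of
#' 100 rectified linear units, mean-squared-error loss, Adam with learning
#' rate 1e-3 and epsilon 1e-4, batch size 64, 10,000 iterations.
#'
#' @param hidden_layers,units Architecture.
#' @param lr,epsilon Adam settings.
#' @param batch Mini-batch size.
#' @param iterations Gradient steps.
#' @param eval_every Validation-loss cadence for the best snapshot.
#' @param seed Integer seed.
#' @return List of class `regressor_config`.
#' @export
regressor_config <- function(hidden_layers = 5, units = 100, lr = 1e-3,
                             epsilon = 1e-4, batch = 64, iterations = 10000,
                             eval_every = 250, seed = 1) {
  stopifnot(hidden_layers >= 1, units >= 1, lr > 0, epsilon > 0,
            batch >= 1, iterations >= 1)
  structure(list(hidden_layers = hidden_layers, units = units, lr = lr,
                 epsilon = epsilon, batch = batch, iterations = iterations,
                 eval_every = eval_every, seed = seed),
            class = "regressor_config")
}

mocap_dofs <- function() {
  as.vector(t(outer(MOCAP_JOINT_ORDER, c("X", "Y", "Z"), paste, sep = "_")))
}

std_fit <- function(M) {
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-9] <- 1
  list(mu = mu, sd = sd)
}

std_apply <- function(M, st) sweep(sweep(M, 2, st$mu), 2, st$sd, `/`)

#' Train the joint-angle regressor
#'
#' Maps sensor channels to joint angles (degrees). Channels and targets are
#' z-scored with training-split statistics (the network never sees raw pF
#' scales); predictions are mapped back to degrees. The snapshot with the
#' lowest validation loss is kept. Seeded and reproducible.
#'
#' @param data Aligned tibble with channel columns, DoF columns and a
#'   `split` column (see [split_dataset()]).
#' @param config A [regressor_config()].
#' @param channels Channel columns (default: all `chNN`).
#' @param dofs Target DoF columns. Default: the 33 DoF of the 11 optically
#'   tracked joints (the root orientation is not skin-observable and the
#'   reference system did not report it).
#' @return Object of class `angle_regressor`.
#' @export
train_angle_regressor <- function(data, config = regressor_config(),
                                  channels = NULL, dofs = NULL) {
  channels <- channels %||% stream_channels(data)
  dofs <- dofs %||% intersect(mocap_dofs(), names(data))
  stopifnot(length(channels) >= 1, length(dofs) >= 1,
            "split" %in% names(data))
  X <- as.matrix(data[, channels]); Y <- as.matrix(data[, dofs])
  if (any(!is.finite(X)) || any(!is.finite(Y))) {
    stop("non-finite values in training data", call. = FALSE)
  }
  tr <- data$split == "train"; va <- data$split == "val"
  st_x <- std_fit(X[tr, , drop = FALSE])
  st_y <- std_fit(Y[tr, , drop = FALSE])
  Xtr <- std_apply(X[tr, , drop = FALSE], st_x)
  Ytr <- std_apply(Y[tr, , drop = FALSE], st_y)
  Xva <- std_apply(X[va, , drop = FALSE], st_x)
  Yva <- std_apply(Y[va, , drop = FALSE], st_y)
  n_layers <- config$hidden_layers + 1L
  sizes <- c(ncol(X), rep(config$units, config$hidden_layers), ncol(Y))
  with_seed(config$seed, {
    params <- nn_init_dense(sizes)
    state <- adam_state(params)
    best <- list(loss = Inf, params = params, iter = 0L)
    hist <- list()
    n_tr <- nrow(Xtr)
    for (it in seq_len(config$iterations)) {
      idx <- sample.int(n_tr, min(config$batch, n_tr))
      H <- mlp_forward(params, Xtr[idx, , drop = FALSE], n_layers)
      err <- H[[n_layers + 1L]] - Ytr[idx, , drop = FALSE]
      dY <- 2 * err / length(err)
      grads <- mlp_backward(params, H, dY, n_layers)
      upd <- adam_step(params, grads, state, lr = config$lr,
                       eps = config$epsilon)
      params <- upd$params; state <- upd$state
      if (it %% config$eval_every == 0L || it == config$iterations) {
        pv <- mlp_forward(params, Xva, n_layers)[[n_layers + 1L]]
        vloss <- mean((pv - Yva)^2)
        hist[[length(hist) + 1L]] <- tibble::tibble(iteration = it,
                                                    val_loss = vloss)
        if (vloss < best$loss) best <- list(loss = vloss, params = params,
                                            iter = it)
      }
    }
    structure(list(params = best$params, n_layers = n_layers,
                   channels = channels, dofs = dofs,
                   std_x = st_x, std_y = st_y, config = config,
                   best_iter = best$iter, best_val_loss = best$loss,
                   history = dplyr::bind_rows(hist)),
              class = "angle_regressor")
  })
}

#' @export
predict.angle_regressor <- function(object, newdata, ...) {
  X <- std_apply(as.matrix(newdata[, object$channels]), object$std_x)
  P <- mlp_forward(object$params, X, object$n_layers)[[object$n_layers + 1L]]
  P <- sweep(sweep(P, 2, object$std_y$sd, `*`), 2, object$std_y$mu, `+`)
  colnames(P) <- object$dofs
  tibble::as_tibble(as.data.frame(P))
}

#' @export
print.angle_regressor <- function(x, ...) {
  cat("<angle_regressor> ", x$config$hidden_layers, " x ", x$config$units,
      " ReLU MLP: ", length(x$channels), " channels -> ", length(x$dofs),
      " DoF (best val loss ", signif(x$best_val_loss, 4), " @ iter ",
      x$best_iter, ")\n", sep = "")
  invisible(x)
}

#' Evaluate the regressor
#'
#' Per-DoF mean absolute error in degrees on a held-out split, with
#' per-joint aggregates and the DoF-weighted overall mean.
#'
#' @param model An `angle_regressor`.
#' @param data Aligned tibble; rows with `split == use_split` are scored
#'   (all rows if there is no split column).
#' @param use_split Which split to score (default `"test"`).
#' @return Object of class `calib_report`: tibbles `per_dof`, `per_joint`,
#'   scalar `overall_mae_deg`.
#' @export
evaluate_regressor <- function(model, data, use_split = "test") {
  if ("split" %in% names(data)) data <- data[data$split == use_split, ]
  truth <- as.matrix(data[, model$dofs])
  pred <- as.matrix(predict(model, data))
  mae <- colMeans(abs(pred - truth))
  per_dof <- tibble::tibble(
    dof = model$dofs,
    joint = sub("_[XYZ]$", "", model$dofs),
    axis = sub("^.*_", "", model$dofs),
    mae_deg = unname(mae)
  )
  per_joint <- dplyr::summarise(dplyr::group_by(per_dof, .data$joint),
                                mae_deg = mean(.data$mae_deg), .groups = "drop")
  structure(list(per_dof = per_dof, per_joint = per_joint,
                 overall_mae_deg = mean(mae), n_frames = nrow(data)),
            class = "calib_report")
}

#' @export
print.calib_report <- function(x, ...) {
  cat("<calib_report> overall MAE ", round(x$overall_mae_deg, 3), " deg over ",
      nrow(x$per_dof), " DoF, ", x$n_frames, " test frames\n", sep = "")
  invisible(x)
}

#' Tidy / summarize calibration reports
#'
#' @param x A `calib_report`.
#' @param ... Unused.
#' @return `tidy()`: per-DoF MAE tibble. `glance()`: one row with the
#'   overall mean MAE, worst DoF and frame count.
#' @method tidy calib_report
#' @export
tidy.calib_report <- function(x, ...) x$per_dof

#' @rdname tidy.calib_report
#' @method glance calib_report
#' @export
glance.calib_report <- function(x, ...) {
  tibble::tibble(overall_mae_deg = x$overall_mae_deg,
                 worst_dof = x$per_dof$dof[which.max(x$per_dof$mae_deg)],
                 worst_mae_deg = max(x$per_dof$mae_deg),
                 n_dof = nrow(x$per_dof), n_frames = x$n_frames)
}

#' @rdname tidy.calib_report
#' @method glance angle_regressor
#' @export
glance.angle_regressor <- function(x, ...) {
  tibble::tibble(hidden_layers = x$config$hidden_layers,
                 units = x$config$units,
                 n_channels = length(x$channels), n_dof = length(x$dofs),
                 best_iter = x$best_iter, best_val_loss = x$best_val_loss)
}

#' @rdname tidy.calib_report
#' @method tidy angle_regressor
#' @export
tidy.angle_regressor <- function(x, ...) x$history

# Central Savitzky-Golay kernel (order `poly`, odd `window`).
sg_kernel <- function(window, poly = 3) {
  h <- (window - 1L) / 2L
  xs <- seq(-h, h) / max(h, 1)
  A <- outer(xs, 0:poly, `^`)
  (A %*% solve(crossprod(A)))[, 1]
}

sg_smooth_once <- function(x, window, poly) {
  n <- length(x)
  k <- sg_kernel(window, poly)
  h <- (window - 1L) / 2L
  xp <- c(rep(x[1], h), x, rep(x[n], h))   # nearest-edge padding
  out <- stats::convolve(xp, rev(k), type = "filter")
  as.numeric(out)
}

#' Slow drift baseline (Savitzky-Golay)
#'
#' Smooths motion out of each channel with an order-3 Savitzky-Golay filter
#' applied `passes` times over a very long window (default 18,000 frames,
#' i.e. 180 s at 100 Hz), with nearest-value edge padding — leaving the slow
#' drift component for visualization or subtraction. Even windows are
#' adjusted up by one; windows longer than the stream are clipped (odd).
#'
#' @param stream A `sensor_stream` or any tibble with `time_s` + channels.
#' @param window Filter window in frames.
#' @param passes Number of smoothing passes (default 2).
#' @param poly Polynomial order (3).
#' @return Tibble of per-channel baselines on the input clock.
#' @export
drift_baseline <- function(stream, window = 18000, passes = 2, poly = 3) {
  n <- nrow(stream)
  if (n <= 3) stop("stream too short", call. = FALSE)
  if (window %% 2 == 0) window <- window + 1
  if (window > n) window <- n - (1 - n %% 2)
  if (window <= poly + 1) window <- poly + 2 + (poly %% 2)
  cols <- setdiff(names(stream), c("time_s", "label", "split"))
  out <- stream[, c("time_s", cols)]
  for (cn in cols) {
    x <- stream[[cn]]
    for (p in seq_len(passes)) x <- sg_smooth_once(x, window, poly)
    out[[cn]] <- x
  }
  out
}
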