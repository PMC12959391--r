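# Pattern recognition: frequency-domain motion profiles (amplitude spectra
# with the stationary-pose offset reported separately) and an LSTM sequence
# classifier over look-back windows of the sensor channels.

#' Frequency profile of a series
#'
#' One-sided amplitude spectrum via the discrete Fourier transform. The DC
#' bin — the stationary pose offset — is reported separately, so dominant
#' components describe the movement itself. For a pure sinusoid of
#' amplitude A the spectrum shows A at its frequency.
#'
#' @param series Numeric vector, or a tibble with `time_s` plus numeric
#'   columns (each profiled separately).
#' @param rate Sampling rate in Hz (required for a bare vector; inferred
#'   from `time_s` otherwise).
#' @return Object of class `spectrum_profile`: tibble `spectrum`
#'   (`channel`, `frequency_hz`, `amplitude`), tibble `offsets`, and the
#'   rate.
#' @export
frequency_profile <- function(series, rate = NULL) {
  if (is.data.frame(series)) {
    t <- series$time_s
    if (length(t) < 16) stop("need at least 16 frames", call. = FALSE)
    dt <- diff(t)
    if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt)) {
      stop("non-uniform timestamps", call. = FALSE)
    }
    rate <- rate %||% (1 / mean(dt))
    cols <- setdiff(names(series), c("time_s", "label", "split"))
    M <- as.matrix(series[, cols])
  } else {
    if (is.null(rate)) stop("rate is required for a bare vector", call. = FALSE)
    if (length(series) < 16) stop("need at least 16 frames", call. = FALSE)
    M <- matrix(series, ncol = 1, dimnames = list(NULL, "series"))
  }
  n <- nrow(M)
  kmax <- floor(n / 2)
  freqs <- (1:kmax) * rate / n
  rows <- purrr::map(colnames(M), function(cn) {
    X <- stats::fft(M[, cn])
    amp <- 2 * Mod(X[2:(kmax + 1)]) / n
    if (n %% 2 == 0) amp[kmax] <- amp[kmax] / 2  # Nyquist bin is not doubled
    tibble::tibble(channel = cn, frequency_hz = freqs, amplitude = amp)
  })
  offsets <- tibble::tibble(channel = colnames(M),
                            offset = unname(colMeans(M)))
  structure(list(spectrum = dplyr::bind_rows(rows), offsets = offsets,
                 rate = rate, n = n),
            class = "spectrum_profile")
}

#' Dominant spectral components
#'
#' @param profile A `spectrum_profile`.
#' @param k Components per channel (DC excluded by construction).
#' @return Tibble of the top-`k` (frequency, amplitude) pairs per channel,
#'   in descending amplitude order.
#' @export
dominant_components <- function(profile, k = 3) {
  dplyr::slice_head(
    dplyr::arrange(dplyr::group_by(profile$spectrum, .data$channel),
                   dplyr::desc(.data$amplitude)),
    n = k) |> dplyr::ungroup()
}

#' Classifier configuration
#'
#' Defaults mirror the study pipeline: an LSTM with three layers and hidden
#' size 50, one fully connected layer and a softmax head, cross-entropy
#' loss, Adam (lr 1e-3, epsilon 1e-4), one look-back step, batch 64, 1000
#' iterations.
#'
#' @param layers,hidden LSTM depth and hidden size.
#' @param lookback Look-back window length in steps (>= 1).
#' @param lr,epsilon Adam settings.
#' @param batch Mini-batch size.
#' @param iterations Gradient steps.
#' @param eval_every Validation cadence for the best snapshot.
#' @param seed Integer seed.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(layers = 3, hidden = 50, lookback = 1,
                              lr = 1e-3, epsilon = 1e-4, batch = 64,
                              iterations = 1000, eval_every = 100, seed = 1) {
  stopifnot(layers >= 1, hidden >= 1, lookback >= 1, lr > 0, batch >= 1,
            iterations >= 1)
  structure(list(layers = layers, hidden = hidden, lookback = lookback,
                 lr = lr, epsilon = epsilon, batch = batch,
                 iterations = iterations, eval_every = eval_every,
                 seed = seed),
            class = "classifier_config")
}

#' Look-back windows
#'
#' Builds one sample per labeled frame `t` from the `L` frames
#' `t-L+1 ... t`, labeled by frame `t`. The first `L-1` frames of each
#' contiguous label segment are dropped and windows never span a segment
#' boundary.
#'
#' @param data Tibble with channel columns, a `label` column, and
#'   optionally `split`.
#' @param lookback Window length `L`.
#' @param channels Channel columns (default all `chNN`).
#' @return List: `X` (n x L x D array), `label` (factor), `split`,
#'   `frame` (row index of the window's last frame).
#' @export
make_windows <- function(data, lookback = 1, channels = NULL) {
  stopifnot(lookback >= 1)
  channels <- channels %||% stream_channels(data)
  lab <- as.character(data$label)
  keep <- !is.na(lab)
  run <- cumsum(c(TRUE, lab[-1] != lab[-length(lab)] |
                    is.na(lab[-1]) != is.na(lab[-length(lab)])))
  pos <- stats::ave(seq_along(run), run, FUN = seq_along)
  t_idx <- which(keep & pos >= lookback)
  M <- as.matrix(data[, channels])
  X <- array(0, dim = c(length(t_idx), lookback, length(channels)))
  for (l in seq_len(lookback)) {
    X[, l, ] <- M[t_idx - lookback + l, , drop = FALSE]
  }
  list(X = X,
       label = factor(lab[t_idx]),
       split = if ("split" %in% names(data)) data$split[t_idx] else NULL,
       frame = t_idx, channels = channels)
}

# slice a windows array into the per-timestep batch matrices the LSTM consumes
steps_of <- function(X, rows) {
  L <- dim(X)[2]
  lapply(seq_len(L), function(l) {
    matrix(X[rows, l, ], nrow = length(rows), ncol = dim(X)[3])
  })
}

#' Train the motion-pattern classifier
#'
#' Stacked LSTM over look-back windows of standardized sensor channels,
#' with a linear + softmax head, trained by cross-entropy/Adam with the
#' best-on-validation snapshot retained. Seeded and reproducible.
#'
#' @param data Tibble with channels, `label` and `split` columns (use
#'   [split_dataset()] with sequential mode for sequence discipline).
#' @param config A [classifier_config()].
#' @param channels Channel columns (default all `chNN`).
#' @return Object of class `motion_classifier`.
#' @export
train_motion_classifier <- function(data, config = classifier_config(),
                                    channels = NULL) {
  w <- make_windows(data, lookback = config$lookback, channels = channels)
  classes <- levels(w$label)
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  if (is.null(w$split)) stop("data must carry a split column", call. = FALSE)
  if (any(!is.finite(w$X))) stop("non-finite values in channels", call. = FALSE)
  tr <- which(w$split == "train"); va <- which(w$split == "val")
  flat_tr <- matrix(w$X[tr, , ], nrow = length(tr) * dim(w$X)[2])
  st_x <- std_fit(flat_tr)
  Xs <- w$X
  for (d in seq_len(dim(Xs)[3])) {
    Xs[, , d] <- (Xs[, , d] - st_x$mu[d]) / st_x$sd[d]
  }
  y <- as.integer(w$label)
  D <- dim(Xs)[3]
  with_seed(config$seed, {
    params <- nn_init_lstm(D, config$hidden, config$layers, length(classes))
    state <- adam_state(params)
    best <- list(loss = Inf, params = params, iter = 0L)
    hist <- list()
    va_steps <- steps_of(Xs, va); yva <- y[va]
    for (it in seq_len(config$iterations)) {
      idx <- tr[sample.int(length(tr), min(config$batch, length(tr)))]
      fwd <- lstm_forward(params, steps_of(Xs, idx), config$hidden,
                          config$layers)
      prob <- softmax_rows(fwd$logits)
      dlogits <- prob
      yb <- y[idx]
      dlogits[cbind(seq_along(idx), yb)] <-
        dlogits[cbind(seq_along(idx), yb)] - 1
      dlogits <- dlogits / length(idx)
      grads <- lstm_backward(params, fwd, dlogits, config$hidden,
                             config$layers)
      upd <- adam_step(params, grads, state, lr = config$lr,
                       eps = config$epsilon)
      params <- upd$params; state <- upd$state
      if (it %% config$eval_every == 0L || it == config$iterations) {
        pv <- lstm_forward(params, va_steps, config$hidden, config$layers)
        vloss <- cross_entropy(softmax_rows(pv$logits), yva)
        hist[[length(hist) + 1L]] <- tibble::tibble(iteration = it,
                                                    val_loss = vloss)
        if (vloss < best$loss) best <- list(loss = vloss, params = params,
                                            iter = it)
      }
    }
    structure(list(params = best$params, classes = classes,
                   channels = w$channels, std_x = st_x, config = config,
                   best_iter = best$iter, best_val_loss = best$loss,
                   history = dplyr::bind_rows(hist)),
              class = "motion_classifier")
  })
}

#' @export
print.motion_classifier <- function(x, ...) {
  cat("<motion_classifier> ", x$config$layers, "-layer LSTM(h=",
      x$config$hidden, "), lookback ", x$config$lookback, ", ",
      length(x$classes), " classes\n", sep = "")
  invisible(x)
}

#' @export
predict.motion_classifier <- function(object, newdata,
                                      type = c("class", "prob"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  if (is.data.frame(newdata)) {
    w <- make_windows(newdata, lookback = cfg$lookback,
                      channels = object$channels)
    X <- w$X
  } else {
    X <- newdata
  }
  for (d in seq_len(dim(X)[3])) {
    X[, , d] <- (X[, , d] - object$std_x$mu[d]) / object$std_x$sd[d]
  }
  prob <- matrix(0, dim(X)[1], length(object$classes))
  chunk <- 20000L
  for (s in seq(1L, dim(X)[1], by = chunk)) {
    rows <- s:min(dim(X)[1], s + chunk - 1L)
    fwd <- lstm_forward(object$params, steps_of(X, rows), cfg$hidden,
                        cfg$layers)
    prob[rows, ] <- softmax_rows(fwd$logits)
  }
  colnames(prob) <- object$classes
  if (type == "prob") return(tibble::as_tibble(as.data.frame(prob)))
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}

#' Evaluate the classifier
#'
#' Frame-window accuracy and the per-class confusion matrix on a held-out
#' split.
#'
#' @param model A `motion_classifier`.
#' @param data Tibble with channels, `label` and `split`.
#' @param use_split Split to score (default `"test"`).
#' @return Object of class `classification_report`: `accuracy`, `confusion`
#'   (true classes in rows), `per_class` tibble.
#' @export
evaluate_classifier <- function(model, data, use_split = "test") {
  w <- make_windows(data, lookback = model$config$lookback,
                    channels = model$channels)
  keep <- if (is.null(w$split)) seq_along(w$label) else which(w$split == use_split)
  X <- w$X[keep, , , drop = FALSE]
  truth <- factor(as.character(w$label[keep]), levels = model$classes)
  pred <- predict(model, X, type = "class")
  conf <- table(truth = truth, predicted = pred)
  per_class <- tibble::tibble(
    class = model$classes,
    n = as.integer(rowSums(conf)),
    correct = as.integer(diag(conf)),
    accuracy = ifelse(rowSums(conf) > 0, diag(conf) / rowSums(conf), NA_real_)
  )
  structure(list(accuracy = mean(pred == truth),
                 confusion = conf, per_class = per_class,
                 n_windows = length(keep)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> accuracy ", round(x$accuracy, 4), " over ",
      x$n_windows, " windows / ", nrow(x$per_class), " classes\n", sep = "")
  invisible(x)
}

#' Tidy / summarize classification reports
#'
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return `tidy()`: per-class accuracy tibble. `glance()`: one-row summary.
#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' @rdname tidy.classification_report
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 n_classes = nrow(x$per_class),
                 classes_majority_correct = sum(x$per_class$accuracy > 0.5,
                                                na.rm = TRUE),
                 n_windows = x$n_windows)
}

#' @rdname tidy.classification_report
#' @method glance motion_classifier
#' @export
glance.motion_classifier <- function(x, ...) {
  tibble::tibble(layers = x$config$layers, hidden = x$config$hidden,
                 lookback = x$config$lookback,
                 n_classes = length(x$classes),
                 best_iter = x$best_iter, best_val_loss = x$best_val_loss)
}
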