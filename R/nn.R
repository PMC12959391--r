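# Minimal neural-network core used by the calibration regressor and the
# pattern classifier: dense ReLU stacks and stacked LSTM cells, trained by
# mini-batch Adam. Matrix-only implementation; gradients are verified
# against finite differences in the test suite.

nn_init_dense <- function(sizes) {
  # He-initialized weight list for a ReLU stack; final layer linear
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    params[[paste0("W", l)]] <- matrix(
      stats::rnorm(fan_in * sizes[l + 1L], 0, sqrt(2 / fan_in)),
      fan_in, sizes[l + 1L])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1L])
  }
  params
}

mlp_forward <- function(params, X, n_layers) {
  H <- vector("list", n_layers + 1L)
  H[[1L]] <- X
  for (l in seq_len(n_layers)) {
    Z <- H[[l]] %*% params[[paste0("W", l)]]
    Z <- sweep(Z, 2, params[[paste0("b", l)]], `+`)
    H[[l + 1L]] <- if (l < n_layers) pmax(Z, 0) else Z
  }
  H
}

mlp_backward <- function(params, H, dY, n_layers) {
  grads <- vector("list", 2L * n_layers)
  names(grads) <- names(params)
  delta <- dY
  for (l in rev(seq_len(n_layers))) {
    grads[[paste0("W", l)]] <- crossprod(H[[l]], delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params[[paste0("W", l)]])) * (H[[l]] > 0)
    }
  }
  grads
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-4) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- LSTM ------------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_init_lstm <- function(input_dim, hidden, n_layers, n_classes) {
  params <- list()
  for (l in seq_len(n_layers)) {
    d_in <- if (l == 1L) input_dim else hidden
    sc <- 1 / sqrt(hidden)
    params[[paste0("Wx", l)]] <- matrix(stats::runif(d_in * 4 * hidden, -sc, sc),
                                        d_in, 4 * hidden)
    params[[paste0("Wh", l)]] <- matrix(stats::runif(hidden * 4 * hidden, -sc, sc),
                                        hidden, 4 * hidden)
    b <- numeric(4 * hidden)
    b[hidden + seq_len(hidden)] <- 1  # forget-gate bias
    params[[paste0("b", l)]] <- b
  }
  params$Wo <- matrix(stats::rnorm(hidden * n_classes, 0, 1 / sqrt(hidden)),
                      hidden, n_classes)
  params$bo <- numeric(n_classes)
  params
}

# X: list over time of B x D matrices. Returns caches for BPTT and logits.
lstm_forward <- function(params, X, hidden, n_layers) {
  B <- nrow(X[[1L]])
  L <- length(X)
  hs <- 1:hidden
  cache <- vector("list", n_layers)
  inp <- X
  for (l in seq_len(n_layers)) {
    h <- matrix(0, B, hidden); cc <- matrix(0, B, hidden)
    steps <- vector("list", L)
    out <- vector("list", L)
    for (t in seq_len(L)) {
      Z <- inp[[t]] %*% params[[paste0("Wx", l)]] +
        h %*% params[[paste0("Wh", l)]]
      Z <- sweep(Z, 2, params[[paste0("b", l)]], `+`)
      i <- sigmoid(Z[, hs, drop = FALSE])
      f <- sigmoid(Z[, hidden + hs, drop = FALSE])
      g <- tanh(Z[, 2 * hidden + hs, drop = FALSE])
      o <- sigmoid(Z[, 3 * hidden + hs, drop = FALSE])
      c_prev <- cc
      cc <- f * c_prev + i * g
      tc <- tanh(cc)
      h <- o * tc
      steps[[t]] <- list(i = i, f = f, g = g, o = o, c = cc, c_prev = c_prev,
                         tc = tc, x = inp[[t]], h_prev = if (t == 1L)
                           matrix(0, B, hidden) else out[[t - 1L]])
      out[[t]] <- h
    }
    cache[[l]] <- steps
    inp <- out
  }
  logits <- sweep(inp[[L]] %*% params$Wo, 2, params$bo, `+`)
  list(cache = cache, top_h = inp[[L]], logits = logits)
}

lstm_backward <- function(params, fwd, dlogits, hidden, n_layers) {
  grads <- lapply(params, function(p) p * 0)
  grads$Wo <- crossprod(fwd$top_h, dlogits)
  grads$bo <- colSums(dlogits)
  L <- length(fwd$cache[[1L]])
  B <- nrow(dlogits)
  hs <- 1:hidden
  # gradient w.r.t. each layer's output sequence; only the last step feeds
  # the head, upper layers feed every step of the layer below
  dout <- vector("list", L)
  for (t in seq_len(L)) dout[[t]] <- matrix(0, B, hidden)
  dout[[L]] <- dlogits %*% t(params$Wo)
  for (l in rev(seq_len(n_layers))) {
    steps <- fwd$cache[[l]]
    dh_next <- matrix(0, B, hidden)
    dc_next <- matrix(0, B, hidden)
    dx <- vector("list", L)
    for (t in rev(seq_len(L))) {
      st <- steps[[t]]
      dh <- dout[[t]] + dh_next
      dc <- dc_next + dh * st$o * (1 - st$tc^2)
      di <- dc * st$g * st$i * (1 - st$i)
      df <- dc * st$c_prev * st$f * (1 - st$f)
      dg <- dc * st$i * (1 - st$g^2)
      do_ <- dh * st$tc * st$o * (1 - st$o)
      dZ <- cbind(di, df, dg, do_)
      grads[[paste0("Wx", l)]] <- grads[[paste0("Wx", l)]] +
        crossprod(st$x, dZ)
      grads[[paste0("Wh", l)]] <- grads[[paste0("Wh", l)]] +
        crossprod(st$h_prev, dZ)
      grads[[paste0("b", l)]] <- grads[[paste0("b", l)]] + colSums(dZ)
      dh_next <- dZ %*% t(params[[paste0("Wh", l)]])
      dc_next <- dc * st$f
      dx[[t]] <- dZ %*% t(params[[paste0("Wx", l)]])
    }
    if (l > 1L) dout <- dx
  }
  grads
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

cross_entropy <- function(prob, y_idx) {
  -mean(log(pmax(prob[cbind(seq_len(nrow(prob)), y_idx)], 1e-12)))
}
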