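test_that("the regressor config defaults echo the study architecture", {
  cfg <- regressor_config()
  expect_identical(cfg$hidden_layers, 5)
  expect_identical(cfg$units, 100)
  expect_identical(cfg$batch, 64)
  expect_identical(cfg$iterations, 10000)
  expect_equal(cfg$lr, 1e-3)
  expect_equal(cfg$epsilon, 1e-4)
})

# Small synthetic linear system: channels are an invertible linear map of
# the angles plus nothing else, so least squares recovers it exactly and
# the MLP must come close.
linear_fixture <- function(n = 3000, seed = 13) {
  set.seed(seed)
  Y <- cbind(LE_X = runif(n, 0, 120), LS_X = runif(n, -60, 60),
             LK_X = runif(n, 0, 130))
  A <- 0.6 * diag(3) + matrix(runif(9, -0.15, 0.15), 3, 3)
  X <- Y %*% A + 100
  colnames(X) <- sprintf("ch%02d", 0:2)
  d <- dplyr::bind_cols(tibble::as_tibble(as.data.frame(X)),
                        tibble::as_tibble(as.data.frame(Y)))
  split_dataset(d, mode = "random", seed = seed)
}

test_that("a noise-free linear system is learned to sub-degree accuracy", {
  d <- linear_fixture()
  model <- train_angle_regressor(
    d, regressor_config(seed = 1),
    dofs = c("LE_X", "LS_X", "LK_X"))
  rep <- evaluate_regressor(model, d)
  expect_lt(rep$overall_mae_deg, 0.3)
  # least-squares oracle: exactly solvable
  tr <- d$split == "train"; te <- d$split == "test"
  fit <- stats::lm(as.matrix(d[tr, c("LE_X", "LS_X", "LK_X")]) ~
                     as.matrix(d[tr, sprintf("ch%02d", 0:2)]))
  pred <- cbind(1, as.matrix(d[te, sprintf("ch%02d", 0:2)])) %*% coef(fit)
  oracle_mae <- mean(abs(pred - as.matrix(d[te, c("LE_X", "LS_X", "LK_X")])))
  expect_lt(oracle_mae, 1e-8)
})

test_that("shuffled labels cannot be learned below the label scale", {
  d <- linear_fixture(n = 2000, seed = 14)
  set.seed(1)
  perm <- sample(nrow(d))
  d[, c("LE_X", "LS_X", "LK_X")] <- d[perm, c("LE_X", "LS_X", "LK_X")]
  model <- train_angle_regressor(
    d, regressor_config(iterations = 1500, seed = 1),
    dofs = c("LE_X", "LS_X", "LK_X"))
  rep <- evaluate_regressor(model, d)
  # MAE of an uninformative predictor is on the order of the label spread
  spread <- mean(apply(as.matrix(d[, c("LE_X", "LS_X", "LK_X")]), 2,
                       function(y) mean(abs(y - mean(y)))))
  expect_gt(rep$overall_mae_deg, 0.5 * spread)
})

test_that("training is reproducible and rejects non-finite inputs", {
  d <- linear_fixture(n = 800, seed = 15)
  cfg <- regressor_config(iterations = 200, seed = 3)
  m1 <- train_angle_regressor(d, cfg, dofs = "LE_X")
  m2 <- train_angle_regressor(d, cfg, dofs = "LE_X")
  expect_identical(m1$params, m2$params)
  expect_identical(evaluate_regressor(m1, d)$overall_mae_deg,
                   evaluate_regressor(m2, d)$overall_mae_deg)
  d$ch00[5] <- NA
  expect_error(train_angle_regressor(d, cfg, dofs = "LE_X"), "non-finite")
})

test_that("evaluation reports exact per-DoF mean absolute errors", {
  d <- linear_fixture(n = 600, seed = 16)
  model <- train_angle_regressor(
    d, regressor_config(iterations = 300, seed = 1),
    dofs = c("LE_X", "LS_X", "LK_X"))
  rep <- evaluate_regressor(model, d)
  te <- d[d$split == "test", ]
  manual <- colMeans(abs(as.matrix(predict(model, te)) -
                           as.matrix(te[, model$dofs])))
  expect_equal(rep$per_dof$mae_deg, unname(manual), tolerance = 1e-12)
  expect_equal(rep$overall_mae_deg, mean(manual), tolerance = 1e-12)
  expect_identical(nrow(glance(rep)), 1L)
  expect_identical(nrow(tidy(rep)), 3L)
})

test_that("the drift baseline is exact on constants and interior ramps", {
  t <- (0:999) / 100
  d <- tibble::tibble(time_s = t, ch00 = rep(7, 1000),
                      ch01 = seq(0, 10, length.out = 1000))
  base <- drift_baseline(d, window = 101)
  expect_equal(base$ch00, d$ch00, tolerance = 1e-9)
  # nearest-edge padding biases ~one window at each end per pass
  interior <- 110:890
  expect_equal(base$ch01[interior], d$ch01[interior], tolerance = 1e-6)
})

test_that("the SG kernel agrees with an explicit local polynomial fit", {
  set.seed(20)
  x <- cumsum(rnorm(200))
  sm <- stretchsuit:::sg_smooth_once(x, 21, 3)
  h <- 10
  for (i in c(50, 101, 150)) {
    idx <- (i - h):(i + h)
    fit <- stats::lm(x[idx] ~ poly(seq(-h, h), 3, raw = TRUE))
    expect_equal(sm[i], unname(predict(fit)[h + 1]), tolerance = 1e-8)
  }
})

test_that("the twice-applied long-window baseline recovers injected drift", {
  t <- (0:7999) / 100
  injected <- 6 / (1 + exp(-(t - 40) / 8))     # slow logistic drift, pF
  x <- sin(2 * pi * 1 * t) + injected
  d <- tibble::tibble(time_s = t, ch00 = x)
  base <- drift_baseline(d, window = 4001, passes = 2)
  interior <- 2200:5800
  err <- max(abs(base$ch00[interior] - injected[interior]))
  expect_lt(err, 0.05 * max(injected))
  # even windows are adjusted, oversized windows clipped, short streams fail
  expect_error(drift_baseline(d[1:3, ]), "short")
  small <- drift_baseline(d[1:500, ], window = 18000)
  expect_identical(nrow(small), 500L)
})
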