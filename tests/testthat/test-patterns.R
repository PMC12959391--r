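test_that("frequency profiles localize sinusoids and report DC separately", {
  t <- (0:999) / 100
  prof <- frequency_profile(sin(2 * pi * 1.5 * t) + 2, rate = 100)
  top <- dominant_components(prof, 1)
  expect_lt(abs(top$frequency_hz - 1.5), 0.1)
  expect_equal(top$amplitude, 1, tolerance = 0.02)
  expect_equal(prof$offsets$offset, 2, tolerance = 1e-6)
  flat <- frequency_profile(rep(4.2, 128), rate = 100)
  expect_lt(max(flat$spectrum$amplitude), 1e-9)
  expect_equal(flat$offsets$offset, 4.2)
  two <- frequency_profile(2 * sin(2 * pi * 1 * t) + sin(2 * pi * 3 * t),
                           rate = 100)
  d2 <- dominant_components(two, 2)
  expect_equal(d2$frequency_hz, c(1, 3), tolerance = 0.05)
  expect_equal(d2$amplitude, c(2, 1), tolerance = 0.05)
  bad <- tibble::tibble(time_s = cumsum(runif(50, 0.005, 0.02)), a = rnorm(50))
  expect_error(frequency_profile(bad), "non-uniform")
  expect_error(frequency_profile(1:5, rate = 10), "16")
})

test_that("the spectrum conserves energy (Parseval)", {
  set.seed(4)
  for (n in c(256, 255)) {        # even and odd lengths
    x <- rnorm(n)
    prof <- frequency_profile(x, rate = 100)
    amp <- prof$spectrum$amplitude
    nyq <- if (n %% 2 == 0) length(amp) else 0L
    power <- prof$offsets$offset^2 + sum(amp^2) / 2 +
      (if (nyq > 0) amp[nyq]^2 - amp[nyq]^2 / 2 else 0)
    expect_equal(power, mean(x^2), tolerance = 1e-6)
  }
})

windows_fixture <- function() {
  tibble::tibble(
    time_s = (0:199) / 100,
    ch00 = rnorm(200), ch01 = rnorm(200),
    label = rep(c("a", "b"), each = 100)
  )
}

test_that("look-back windows respect labels and boundaries", {
  set.seed(5)
  d <- windows_fixture()
  w1 <- make_windows(d, lookback = 1)
  expect_identical(dim(w1$X), c(200L, 1L, 2L))
  expect_identical(as.vector(table(w1$label)), c(100L, 100L))
  w10 <- make_windows(d, lookback = 10)
  expect_identical(dim(w10$X)[1], 182L)           # 91 windows per segment
  # no window mixes frames across the a/b boundary
  expect_true(all(w10$frame[w10$label == "b"] >= 110))
  expect_equal(w10$X[1, , 1], d$ch00[1:10])
})

classifier_fixture <- function(n_per = 600, seed = 6) {
  set.seed(seed)
  t <- (seq_len(n_per) - 1) / 100
  mk <- function(f, lab, amp) tibble::tibble(
    time_s = t,
    ch00 = amp * sin(2 * pi * f * t) + rnorm(n_per, 0, 0.05),
    ch01 = amp * cos(2 * pi * f * t) + rnorm(n_per, 0, 0.05),
    label = lab
  )
  d <- dplyr::bind_rows(mk(1, "slow", 1), mk(1, "fast", 3))
  d$time_s <- (seq_len(nrow(d)) - 1) / 100
  split_dataset(d, mode = "sequential")
}

test_that("well-separated classes are classified perfectly", {
  d <- classifier_fixture()
  model <- train_motion_classifier(
    d, classifier_config(iterations = 400, seed = 1))
  rep <- evaluate_classifier(model, d)
  expect_equal(rep$accuracy, 1)
  expect_identical(sum(diag(rep$confusion)), rep$n_windows)
  # nearest-centroid oracle on the amplitude feature agrees
  tr <- d$split == "train"; te <- d$split == "test"
  r_tr <- sqrt(d$ch00^2 + d$ch01^2)[tr]
  cent <- tapply(r_tr, d$label[tr], mean)
  pred <- names(cent)[apply(abs(outer(sqrt(d$ch00^2 + d$ch01^2)[te],
                                      cent, `-`)), 1, which.min)]
  expect_equal(mean(pred == d$label[te]), 1)
})

test_that("classifier configuration and probability head behave", {
  cfg <- classifier_config()
  expect_identical(cfg$layers, 3)
  expect_identical(cfg$hidden, 50)
  expect_identical(cfg$lookback, 1)
  expect_identical(cfg$iterations, 1000)
  d <- classifier_fixture(n_per = 300, seed = 7)
  model <- train_motion_classifier(
    d, classifier_config(iterations = 100, seed = 2))
  prob <- predict(model, d[d$split == "test", ], type = "prob")
  expect_equal(rowSums(as.matrix(prob)), rep(1, nrow(prob)), tolerance = 1e-6)
  rep <- evaluate_classifier(model, d)
  expect_identical(as.integer(rowSums(rep$confusion)), rep$per_class$n)
  single <- d; single$label <- "only"
  expect_error(train_motion_classifier(single), "2 classes")
})

test_that("accuracy is invariant to per-channel affine rescaling", {
  d <- classifier_fixture(n_per = 400, seed = 8)
  cfg <- classifier_config(iterations = 150, seed = 3)
  m1 <- train_motion_classifier(d, cfg)
  a1 <- evaluate_classifier(m1, d)$accuracy
  d2 <- d
  d2$ch00 <- 12 * d$ch00 - 7
  d2$ch01 <- 0.05 * d$ch01 + 3
  m2 <- train_motion_classifier(d2, cfg)
  a2 <- evaluate_classifier(m2, d2)$accuracy
  # train-split z-scoring absorbs the rescale (up to floating-point jitter
  # in the recomputed mean/sd)
  expect_equal(a1, a2, tolerance = 0.02)
})

test_that("training is seed-reproducible", {
  d <- classifier_fixture(n_per = 300, seed = 9)
  cfg <- classifier_config(iterations = 80, seed = 4)
  m1 <- train_motion_classifier(d, cfg)
  m2 <- train_motion_classifier(d, cfg)
  expect_identical(m1$params, m2$params)
})
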