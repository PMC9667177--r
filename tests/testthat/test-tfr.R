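test_that("Morlet power matches a brute-force wavelet inner product", {
  fs <- 100; n <- 800
  set.seed(3)
  x <- rnorm(n)
  ep <- epochs(array(x, c(1, 1, n)), fs, -2, "C1", data.frame(i = 1))
  tfr <- morlet_tfr(ep, freqs = c(6, 13), time_step = 0.05, width = 5)
  for (fi in 1:2) {
    f0 <- tfr$freqs[fi]
    sig_t <- 5 / (2 * pi * f0)
    L <- floor(4 * sig_t * fs)
    m <- -L:L
    w <- exp(-(m / fs)^2 / (2 * sig_t^2)) * exp(1i * 2 * pi * f0 * m / fs)
    w <- w / sqrt(sum(abs(w)^2))
    for (tt in c(-1, 0, 1.5)) {
      b <- which(abs(tfr$times - tt) < 1e-9)
      c0 <- round((tt + 2) * fs) + 1
      bf <- abs(sum(x[(c0 - L):(c0 + L)] * Conj(w)))^2
      expect_equal(tfr$power[1, 1, fi, b], bf, tolerance = 1e-10)
    }
  }
})

test_that("a pure sinusoid peaks at its own frequency row", {
  fs <- 100; n <- 800
  t <- (0:(n - 1)) / fs - 2
  ep <- epochs(array(3 * cos(2 * pi * 10 * t), c(1, 1, n)), fs, -2, "C1",
               data.frame(i = 1))
  tfr <- morlet_tfr(ep, freqs = 4:30)
  mid <- tfr$times > -1 & tfr$times < 1
  ridge <- apply(tfr$power[1, 1, , mid], 1, mean)
  expect_lte(abs(tfr$freqs[which.max(ridge)] - 10), 1)
})

test_that("zero signal gives zero power; invalid edges are flagged", {
  ep <- epochs(array(0, c(2, 2, 800)), 100, -2, c("A", "B"),
               data.frame(i = 1:2))
  tfr <- morlet_tfr(ep, freqs = c(4, 20))
  expect_true(all(tfr$power == 0))
  # 4 Hz wavelet spans +/- 0.8 s: bins within that margin are invalid
  expect_false(tfr$valid[1, 1])
  expect_true(all(tfr$valid[1, tfr$times > -1.2 & tfr$times < 5.2]))
  # higher frequency -> tighter wavelet -> more valid bins
  expect_gte(sum(tfr$valid[2, ]), sum(tfr$valid[1, ]))
  expect_error(morlet_tfr(ep, freqs = c(-1, 10)), "freqs > 0")
  expect_error(morlet_tfr(ep, freqs = 10, width = 0.5), "width")
})

test_that("two-tone ridge powers follow the analytic L2-Morlet response", {
  # an L2-normalised Morlet responds to amplitude A at centre frequency f
  # with power A^2 / 4 * 2 sqrt(pi) sigma_t * fs (discrete sampling), so the
  # ridge ratio carries amplitudes squared times sigma_t (i.e. 1/f)
  fs <- 200; n <- 1600
  t <- (0:(n - 1)) / fs - 2
  a6 <- 2; a30 <- 1
  x <- a6 * cos(2 * pi * 6 * t) + a30 * cos(2 * pi * 30 * t)
  ep <- epochs(array(x, c(1, 1, n)), fs, -2, "C1", data.frame(i = 1))
  tfr <- morlet_tfr(ep, freqs = c(6, 30))
  mid <- tfr$times > -0.5 & tfr$times < 1.5
  p6 <- mean(tfr$power[1, 1, 1, mid])
  p30 <- mean(tfr$power[1, 1, 2, mid])
  sig <- function(f) 5 / (2 * pi * f)
  expected_ratio <- (a6^2 * sig(6)) / (a30^2 * sig(30))
  expect_lt(abs(p6 / p30 - expected_ratio) / expected_ratio, 0.1)
})

test_that("total white-noise power grows linearly with variance", {
  fs <- 100; n <- 800
  set.seed(11)
  vars <- c(0.5, 1, 2, 4, 8)
  tot <- vapply(vars, function(v) {
    x <- rnorm(n, sd = sqrt(v))
    ep <- epochs(array(x, c(1, 1, n)), fs, -2, "C1", data.frame(i = 1))
    tfr <- morlet_tfr(ep, freqs = seq(5, 40, 5))
    mean(tfr$power[1, 1, , tfr$times > -1 & tfr$times < 5])
  }, 0)
  fit <- summary(lm(tot ~ vars))
  expect_gt(fit$r.squared, 0.99)
})

test_that("window averaging equals the brute-force bin mean, single bin slices exactly", {
  set.seed(7)
  ep <- epochs(array(rnorm(3 * 2 * 800), c(3, 2, 800)), 100, -2,
               c("A", "B"), data.frame(i = 1:3))
  tfr <- morlet_tfr(ep, freqs = c(8, 12, 16))
  fm <- window_average_features(tfr, 0, 1)
  sel <- which(tfr$times >= 0 - 1e-9 & tfr$times <= 1 + 1e-9)
  # brute force: loop the mean over bins, channel-major order
  for (tr in 1:3) {
    k <- 0
    for (ch in 1:2) for (fi in 1:3) {
      k <- k + 1
      expect_equal(fm$values[tr, k], mean(tfr$power[tr, ch, fi, sel]),
                   tolerance = 1e-12)
    }
  }
  # a one-bin window equals that bin's slice, and bin_features agrees
  t1 <- tfr$times[sel[1]]
  one <- window_average_features(tfr, t1, t1)
  slice <- bin_features(tfr, t1)
  expect_equal(one$values, slice$values)
  expect_identical(one$feature_index, slice$feature_index)
  expect_error(bin_features(tfr, t1 + 0.013), "not on the bin grid")
  expect_error(window_average_features(tfr, 90, 91), "empty")
})

test_that("constant-in-time power averages to the constant", {
  tfr <- structure(list(
    power = array(rep(1:6, times = 10), c(1, 2, 3, 10)),
    freqs = c(5, 10, 15), times = seq(0, 0.45, 0.05),
    valid = matrix(TRUE, 3, 10), fs = 100,
    channel_names = c("A", "B"), metadata = data.frame(i = 1)),
    class = "tfr_stack")
  fm <- window_average_features(tfr, 0, 0.45)
  # array fills trial, channel, freq fastest -> value at (1, ch, fi) constant
  expect_equal(as.numeric(fm$values),
               as.numeric(tfr$power[1, , , 1][cbind(rep(1:2, each = 3),
                                                    rep(1:3, 2))]))
})

test_that("85 retrieval bins fit inside the -2..6 s epoch at every frequency", {
  ep <- epochs(array(rnorm(2 * 1 * 800), c(2, 1, 800)), 100, -2, "C1",
               data.frame(i = 1:2))
  tfr <- morlet_tfr(ep, freqs = c(4, 45))
  grid <- seq(-0.2, 4, by = 0.05)
  expect_length(grid, 85)
  sel <- vapply(tfr$times, function(t) any(abs(grid - t) < 1e-9), TRUE)
  expect_equal(sum(sel), 85)
  expect_true(all(tfr$valid[, sel]))
  mats <- lapply(grid, function(t) bin_features(tfr, t))
  expect_length(mats, 85)
})

test_that("across-trial normalisation z-scores on training statistics only", {
  set.seed(5)
  idx <- data.frame(channel = rep(c("A", "B"), each = 2),
                    freq = rep(c(5, 10), 2))
  train <- eegreplay:::new_feature_matrix(matrix(rnorm(40), 10, 4), idx)
  test <- eegreplay:::new_feature_matrix(matrix(rnorm(20), 5, 4), idx)
  nrm <- normalize_across_trials(train, list(test))
  # columnwise oracle
  for (j in 1:4) {
    mu <- mean(train$values[, j]); s <- sd(train$values[, j])
    expect_equal(nrm$train$values[, j], (train$values[, j] - mu) / s)
    expect_equal(nrm$others[[1]]$values[, j], (test$values[, j] - mu) / s)
  }
  # two-point column: sample-SD convention gives -1/sqrt(2), +1/sqrt(2)
  two <- eegreplay:::new_feature_matrix(matrix(c(1, 3), 2, 1), idx[1, ])
  z <- normalize_across_trials(two)$train$values
  expect_equal(as.numeric(z), c(-1, 1) / sqrt(2))
  # train statistics applied to an identical copy reproduce self-normalisation
  again <- normalize_across_trials(train, list(train))
  expect_equal(again$others[[1]]$values, again$train$values)
  expect_error(normalize_across_trials(
    eegreplay:::new_feature_matrix(matrix(1, 1, 4), idx)), ">= 2")
  # constant features are dropped to zero
  cst <- train; cst$values[, 2] <- 7
  out <- normalize_across_trials(cst, list(test))
  expect_true(all(out$train$values[, 2] == 0))
  expect_true(all(out$others[[1]]$values[, 2] == 0))
  expect_equal(out$stats$dropped, 1)
})

test_that("pooled normalisation uses all matrices for the statistics", {
  idx <- data.frame(channel = "A", freq = 5)
  tr <- eegreplay:::new_feature_matrix(matrix(c(0, 1, 2), 3, 1), idx)
  te <- eegreplay:::new_feature_matrix(matrix(c(10, 11), 2, 1), idx)
  pooled <- normalize_across_trials(tr, list(te), pooled = TRUE)
  allv <- c(0, 1, 2, 10, 11)
  expect_equal(as.numeric(pooled$train$values),
               (c(0, 1, 2) - mean(allv)) / sd(allv))
})

test_that("log-baseline correction matches the elementwise definition", {
  set.seed(8)
  pw <- array(rexp(2 * 1 * 2 * 20) + 0.1, c(2, 1, 2, 20))
  tfr <- structure(list(power = pw, freqs = c(5, 10),
                        times = seq(-1, 0.9, 0.1),
                        valid = matrix(TRUE, 2, 20), fs = 100,
                        channel_names = "A", metadata = data.frame(i = 1:2)),
                   class = "tfr_stack")
  base_sel <- which(tfr$times <= 0)
  out <- log_baseline_tfr(tfr, c(-1, 0))
  for (tr in 1:2) for (fi in 1:2) {
    expected <- log(pw[tr, 1, fi, ]) - mean(log(pw[tr, 1, fi, base_sel]))
    expect_equal(out$power[tr, 1, fi, ], expected, tolerance = 1e-12)
  }
  # constant power -> all zeros; doubling after baseline -> log(2)
  cst <- tfr; cst$power[] <- 3
  expect_true(all(abs(log_baseline_tfr(cst, c(-1, 0))$power) < 1e-12))
  dbl <- tfr; dbl$power[] <- 2; dbl$power[, , , tfr$times <= 0] <- 1
  o <- log_baseline_tfr(dbl, c(-1, 0))
  expect_equal(o$power[1, 1, 1, 20], log(2))
  zp <- tfr; zp$power[1, 1, 1, 1] <- 0
  expect_warning(log_baseline_tfr(zp, c(-1, 0)), "floored")
})

test_that("feature order is stable across stacks and runs", {
  ep <- random_epochs(n_trials = 2, n_channels = 4, n_samples = 400,
                      t0 = -2, channels = c("A", "B", "C", "D"))
  tfr <- morlet_tfr(ep, freqs = c(8, 12))
  f1 <- window_average_features(tfr, 0, 1)$feature_index
  f2 <- bin_features(tfr, 0.5)$feature_index
  expect_identical(f1, f2)
  expect_equal(f1$channel, rep(c("A", "B", "C", "D"), each = 2))
  expect_equal(f1$freq, rep(c(8, 12), 4))
})
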