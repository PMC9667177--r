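# build a synthetic null_distribution at the accuracy level: exchangeable
# per-subject accuracy series around chance
make_null <- function(n_iter, n_sub, times, sd = 5, seed = 1) {
  set.seed(seed)
  acc <- array(rnorm(n_iter * n_sub * length(times), 100 / 3, sd),
               c(n_iter, n_sub, length(times)))
  tmat <- t(apply(acc, 1, function(a) group_t(a)$t))
  structure(list(t = tmat, acc = acc, times = times, n_iter = n_iter,
                 chance = 100 / 3),
            class = "null_distribution")
}

test_that("LOSO selection finds a shared strong effect and stays inside the margin", {
  times <- seq(-0.2, 4, 0.05)
  null <- make_null(60, 6, times, seed = 2)
  set.seed(3)
  acc <- matrix(rnorm(6 * 85, 100 / 3, 5), 6, 85)
  win_bins <- which(times >= 0.9 & times <= 1.0)
  acc[, win_bins] <- acc[, win_bins] + 30
  sel <- loso_select(acc, null, c(0.9, 1.0), margin = 0.2)
  for (s in 1:6) {
    expect_true(all(times[sel$selected[[s]]] >= 0.7 - 1e-9))
    expect_true(all(times[sel$selected[[s]]] <= 1.2 + 1e-9))
    expect_true(any(sel$selected[[s]] %in% win_bins))
    expect_false(sel$fallback[s])
  }
  # margin = 0 keeps selections inside the reference window exactly
  sel0 <- loso_select(acc, null, c(0.9, 1.0), margin = 0)
  for (s in 1:6)
    expect_true(all(times[sel0$selected[[s]]] >= 0.9 - 1e-9 &
                      times[sel0$selected[[s]]] <= 1.0 + 1e-9))
  expect_error(loso_select(acc[1:2, ], make_null(60, 2, times), c(0.9, 1)),
               "3 subjects")
})

test_that("selection for a subject never uses that subject's own data", {
  times <- seq(-0.2, 4, 0.05)
  null <- make_null(60, 5, times, seed = 4)
  set.seed(5)
  acc <- matrix(rnorm(5 * 85, 100 / 3, 5), 5, 85)
  acc[, 20:24] <- acc[, 20:24] + 25
  ref <- c(times[20], times[24])
  s1 <- loso_select(acc, null, ref)
  acc2 <- acc
  acc2[3, ] <- acc2[3, ] + rnorm(85, 0, 40)  # wreck subject 3's series
  s2 <- suppressWarnings(loso_select(acc2, null, ref))
  expect_identical(s1$selected[[3]], s2$selected[[3]])
})

test_that("zero-signal selections fall back to the reference centre", {
  times <- seq(-0.2, 4, 0.05)
  null <- make_null(60, 6, times, seed = 6)
  set.seed(7)
  acc <- matrix(rnorm(6 * 85, 100 / 3, 5), 6, 85)
  expect_warning(sel <- loso_select(acc, null, c(0.9, 1.0)), "fell back")
  centre <- which.min(abs(times - 0.95))
  expect_true(any(vapply(sel$selected, identical, TRUE, centre)))
})

test_that("the success contrast excludes low-trial subjects and handles degenerate input", {
  times <- seq(0, 1, 0.05)
  null <- make_null(50, 6, times, seed = 8)
  set.seed(9)
  accS <- matrix(rnorm(6 * 21, 40, 4), 6, 21)
  accF <- matrix(rnorm(6 * 21, 33, 4), 6, 21)
  loso <- suppressWarnings(loso_select(accS, null, c(0.4, 0.6)))
  res <- success_contrast(accS, accF, n_success = rep(20, 6),
                          n_fail = c(5, rep(20, 5)), loso, min_trials = 10)
  expect_equal(res$n, 5)
  expect_equal(res$n_excluded, 1)
  expect_equal(res$df, 4)
  expect_gt(res$statistic, 0)
  # identical series -> t = 0
  res0 <- success_contrast(accS, accS, rep(20, 6), rep(20, 6), loso,
                           min_trials = 10)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  expect_error(success_contrast(accS, accF, rep(2, 6), rep(2, 6), loso),
               "fewer than 3")
})

test_that("a real success-gated effect is detected via LOSO windows", {
  # the signal fixture injects target reinstatement only on successful trials
  fx <- signal_fixture()
  obs_s <- observed_timecourse(fx$preps, "DE", "success")
  obs_f <- observed_timecourse(fx$preps, "DE", "fail")
  null <- shuffle_null_timecourse(fx$preps, "DE", n_iter = 50, seed = 12)
  loso <- suppressWarnings(loso_select(obs_s$acc, null, c(0.9, 1.0)))
  n_s <- vapply(fx$preps, function(p)
    sum(p$ret_md$condition == "DE" & p$ret_md$success), 0)
  n_f <- vapply(fx$preps, function(p)
    sum(p$ret_md$condition == "DE" & !p$ret_md$success), 0)
  res <- success_contrast(obs_s$acc, obs_f$acc, n_s, n_f, loso,
                          min_trials = 1)
  expect_gt(res$mean_success, res$mean_fail)
})

test_that("shuffled outcomes keep the success contrast at its nominal level", {
  # exchangeable success/fail series on the retrieval grid with a narrow
  # reference window: the LOSO-selected contrast must reject at ~5%
  times <- seq(-0.2, 4, 0.05)
  set.seed(13)
  ps <- vapply(1:200, function(r) {
    null <- make_null(50, 6, times, seed = 1000 + r)
    accS <- matrix(rnorm(6 * 85, 100 / 3, 4), 6, 85)
    accF <- matrix(rnorm(6 * 85, 100 / 3, 4), 6, 85)
    loso <- suppressWarnings(loso_select(accS, null, c(0.9, 1.0)))
    success_contrast(accS, accF, rep(20, 6), rep(20, 6), loso,
                     min_trials = 10)$p
  }, 0)
  k <- sum(ps < 0.05)
  expect_gte(k, qbinom(0.025, 200, 0.05))
  expect_lte(k, qbinom(0.975, 200, 0.05))
})

test_that("rm-ANOVA matches the brute-force sums of squares and paired t", {
  set.seed(14)
  # one-way three-level within design vs a manual decomposition
  n <- 10
  df1 <- data.frame(subject = rep(1:n, each = 3),
                    cond = rep(c("AB", "AC", "DE"), n),
                    value = rnorm(3 * n, rep(c(60, 52, 64), n), 8))
  res1 <- rm_anova(df1, "cond")
  y <- matrix(df1$value, 3, n)  # conditions x subjects
  gm <- mean(y)
  ss_cond <- n * sum((rowMeans(y) - gm)^2)
  ss_subj <- 3 * sum((colMeans(y) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_oracle <- (ss_cond / 2) / (ss_err / (2 * (n - 1)))
  expect_equal(res1$statistic, f_oracle, tolerance = 1e-8)
  expect_equal(res1$df1, 2)
  expect_equal(res1$df2, 2 * (n - 1))
  expect_equal(res1$effect_size, ss_cond / (ss_cond + ss_err),
               tolerance = 1e-8)

  # single two-level factor: F equals the squared paired t
  df2 <- data.frame(subject = rep(1:8, each = 2),
                    mem = rep(c("success", "fail"), 8),
                    value = rnorm(16, rep(c(40, 34), 8), 5))
  res2 <- rm_anova(df2, "mem")
  tt <- t.test(df2$value[df2$mem == "success"],
               df2$value[df2$mem == "fail"], paired = TRUE)
  expect_equal(res2$statistic, unname(tt$statistic)^2, tolerance = 1e-8)

  # pure crossover interaction without noise: interaction huge, mains nil
  df3 <- expand.grid(subject = 1:6, a = c("lo", "hi"), b = c("x", "y"))
  df3$value <- ifelse(df3$a == "hi", 1, -1) * ifelse(df3$b == "y", 1, -1) +
    0.01 * rnorm(nrow(df3))
  res3 <- rm_anova(df3, c("a", "b"))
  inter <- res3[res3$effect == "a:b", ]
  expect_lt(inter$p, 1e-6)
  expect_gt(inter$statistic, res3$statistic[res3$effect == "a"] * 100)
  expect_error(rm_anova(df3[-1, ], c("a", "b")), "balanced")
})

test_that("rm-ANOVA term-level type-I error is nominal on null data", {
  set.seed(15)
  hits <- matrix(FALSE, 120, 3)
  for (r in 1:120) {
    df <- expand.grid(subject = 1:8, a = c("l", "h"), b = c("x", "y"))
    df$value <- rnorm(nrow(df))
    res <- rm_anova(df, c("a", "b"))
    hits[r, ] <- res$p < 0.05
  }
  for (j in 1:3)
    expect_lte(sum(hits[, j]), qbinom(0.9995, 120, 0.05))
})

test_that("one-sample t against chance matches closed forms", {
  res <- one_sample_t(rep(100 / 3, 5))
  expect_equal(res$statistic, 0)
  expect_equal(res$effect_size, 0)
  # two-point closed form
  v <- c(34.4, 38.4)
  m <- mean(v); s <- sd(v)
  res2 <- one_sample_t(v, mu = 33.3)
  expect_equal(res2$statistic, (m - 33.3) / (s / sqrt(2)), tolerance = 1e-12)
  expect_equal(res2$df, 1)
  # noncentrality: N(35, 2) with mu 33.3 has population d = 0.85
  set.seed(16)
  ds <- vapply(1:1000, function(i) {
    x <- rnorm(28, 35, 2)
    one_sample_t(x, 33.3)$effect_size
  }, 0)
  expect_lt(abs(mean(ds) - 0.85), 3 * sd(ds) / sqrt(1000) + 0.03)
  # zero-variance flag
  res3 <- one_sample_t(rep(40, 4), 100 / 3)
  expect_true(res3$degenerate)
  expect_equal(res3$statistic, Inf)
})
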