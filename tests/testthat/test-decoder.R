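# random separable 3-class feature matrix
make_sep_features <- function(n_per = 12, d = 60, gap = 6, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, 3, d)
  centers[1, 1:10] <- gap
  centers[2, 11:20] <- gap
  centers[3, 21:30] <- gap
  lab <- rep(c("city", "forest", "underwater"), each = n_per)
  X <- centers[rep(1:3, each = n_per), ] + matrix(rnorm(3 * n_per * d),
                                                  3 * n_per, d)
  idx <- data.frame(channel = rep(paste0("c", seq_len(d / 10)), each = 10),
                    freq = rep(1:10, d / 10))
  list(fm = eegreplay:::new_feature_matrix(X, idx), labels = lab)
}

test_that("well-separated classes are fit perfectly; degenerate input refused", {
  sp <- make_sep_features()
  dec <- train_ova_linear(sp$fm, sp$labels, C = 1)
  expect_equal(predict(dec, sp$fm), sp$labels)
  expect_equal(dim(dec$W), c(60L, 3L))
  expect_equal(dec$classes, c("city", "forest", "underwater"))
  expect_error(train_ova_linear(sp$fm, rep("city", 36)), "two classes")
  bad <- sp$fm; bad$values[1, 1] <- NA
  expect_error(train_ova_linear(bad, sp$labels), "non-finite")
})

test_that("training accuracy stays perfect on separable data for C in 0.1, 1, 10", {
  sp <- make_sep_features(seed = 2)
  for (C in c(0.1, 1, 10)) {
    dec <- train_ova_linear(sp$fm, sp$labels, C = C)
    expect_equal(predict(dec, sp$fm), sp$labels)
  }
})

test_that("decisions agree with libsvm on the same binary problems", {
  skip_if_not_installed("e1071")
  set.seed(12)
  for (r in 1:5) {
    n <- 40; d <- 25
    x <- matrix(rnorm(n * d), n, d)
    y <- rep(c(1, -1), length.out = n)
    x[y == 1, 1] <- x[y == 1, 1] + 1.5
    K <- tcrossprod(x)
    fit <- eegreplay:::.svc_fit_cpp(K, y, 1)
    own <- as.numeric(K %*% fit$alpha_y + fit$b)
    ref <- e1071::svm(x, factor(y, levels = c(1, -1)), kernel = "linear",
                      cost = 1, scale = FALSE)
    dv <- as.numeric(attr(predict(ref, x, decision.values = TRUE),
                          "decision.values"))
    expect_gt(cor(own, dv), 0.999)
    expect_lt(max(abs(own - dv)), 0.05)
  }
})

test_that("duplicated feature columns leave predictions unchanged", {
  sp <- make_sep_features(n_per = 8, d = 30, seed = 3)
  dup_vals <- cbind(sp$fm$values, sp$fm$values)
  dup <- eegreplay:::new_feature_matrix(dup_vals,
                                        rbind(sp$fm$feature_index,
                                              sp$fm$feature_index))
  d1 <- train_ova_linear(sp$fm, sp$labels)
  d2 <- train_ova_linear(dup, sp$labels)
  expect_equal(predict(d1, sp$fm), predict(d2, dup))
})

test_that("consistently permuting features leaves predictions unchanged", {
  sp <- make_sep_features(n_per = 8, d = 30, seed = 13)
  perm <- sample(30)
  fm_p <- eegreplay:::new_feature_matrix(sp$fm$values[, perm],
                                         sp$fm$feature_index[perm, ])
  d1 <- train_ova_linear(sp$fm, sp$labels)
  d2 <- train_ova_linear(fm_p, sp$labels)
  test <- sp$fm
  test$values <- test$values + 0.1
  test_p <- eegreplay:::new_feature_matrix(test$values[, perm],
                                           test$feature_index[perm, ])
  expect_equal(predict(d1, test), predict(d2, test_p))
  # the weight vectors are the same weights permuted, up to the dual
  # solver's convergence tolerance
  expect_lt(max(abs(d1$W[perm, ] - d2$W)), 1e-2)
  expect_gt(cor(as.vector(d1$W[perm, ]), as.vector(d2$W)), 0.9999)
})

test_that("exact decision ties break to the lowest class index", {
  dec <- structure(list(W = matrix(0, 2, 3), b = c(0, 0, 0),
                        classes = c("a", "b", "c"),
                        norm = list(mean = c(0, 0), sd = c(1, 1),
                                    dead = c(FALSE, FALSE)),
                        C = 1,
                        feature_index = data.frame(channel = "x",
                                                   freq = 1:2)),
                   class = "trained_decoder")
  fm <- eegreplay:::new_feature_matrix(matrix(1, 4, 2), dec$feature_index)
  expect_equal(predict(dec, fm), rep("a", 4))
})

test_that("cross-validation partitions trials into near-equal folds, each tested once", {
  sp <- make_sep_features(n_per = 22, d = 30, seed = 4)  # n = 66
  conf <- cross_validate_10fold(sp$fm, sp$labels, seed = 5)
  expect_equal(sum(conf$counts), 66)
  expect_false(conf$normalized)
  # perfectly separable -> diagonal confusion
  expect_equal(sum(diag(conf$counts)), 66)
  # fold sizes for n = 64: six folds of 6 and four of 7
  fold <- eegreplay:::with_seed(5, rep_len(seq_len(10), 64)[sample.int(64)])
  expect_equal(sort(as.vector(table(fold))), c(rep(6L, 6), rep(7L, 4)))
  expect_error(cross_validate_10fold(
    eegreplay:::new_feature_matrix(sp$fm$values[1:6, ],
                                   sp$fm$feature_index),
    sp$labels[1:6]), "fewer trials")
})

test_that("label shuffling pushes cross-validated accuracy to chance", {
  set.seed(6)
  n <- 36; d <- 20
  idx <- data.frame(channel = rep("c", d), freq = 1:d)
  accs <- vapply(1:25, function(r) {
    fm <- eegreplay:::new_feature_matrix(matrix(rnorm(n * d), n, d), idx)
    lab <- sample(rep(c("a", "b", "c"), each = n / 3))
    confusion_accuracy(normalize_confusion(
      cross_validate_10fold(fm, lab, seed = r)))
  }, 0)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 100 / 3), 3 * se + 1e-9)
})

test_that("confusion normalisation and accuracy follow the worked arithmetic", {
  counts <- matrix(c(2, 0, 1, 1, 4, 1, 1, 0, 2), 3, 3,
                   dimnames = list(true = c("a", "b", "c"),
                                   predicted = c("a", "b", "c")))
  conf <- structure(list(counts = counts, normalized = FALSE,
                         classes = c("a", "b", "c")),
                    class = "confusion_matrix")
  nrm <- normalize_confusion(conf)
  expect_equal(unname(nrm$counts),
               matrix(c(.5, 0, .25, .25, 1, .25, .25, 0, .5), 3, 3))
  expect_true(all(abs(rowSums(nrm$counts) - 1) < 1e-9))
  expect_equal(confusion_accuracy(nrm), 100 * mean(c(.5, 1, .5)))
  # identity counts -> identity proportions -> 100%
  eye <- conf; eye$counts <- diag(3) * 4
  expect_equal(confusion_accuracy(normalize_confusion(eye)), 100)
  # uniform matrix -> 33.33%
  uni <- conf; uni$counts <- matrix(1, 3, 3)
  expect_equal(confusion_accuracy(normalize_confusion(uni)), 100 / 3)
  empty <- conf; empty$counts[2, ] <- 0
  expect_error(normalize_confusion(empty), "empty row")
  expect_error(confusion_accuracy(conf), "normalise")
})

test_that("channel searchlight localises signal and honours the adjacency", {
  set.seed(7)
  n <- 36; chans <- paste0("c", 1:6)
  idx <- data.frame(channel = rep(chans, each = 4),
                    freq = rep(1:4, 6))
  X <- matrix(rnorm(n * 24), n, 24)
  lab <- rep(c("a", "b", "c"), each = 12)
  # signal only in channels c1 and c2
  sig_cols <- idx$channel %in% c("c1", "c2")
  X[lab == "a", sig_cols] <- X[lab == "a", sig_cols] + 4
  X[lab == "b", idx$channel == "c1"] <- X[lab == "b", idx$channel == "c1"] - 4
  fm <- eegreplay:::new_feature_matrix(X, idx)
  nb <- list(c1 = "c2", c2 = "c1", c3 = "c4", c4 = "c3", c5 = "c6",
             c6 = "c5")
  sl <- searchlight_channels(fm, lab, nb, seed = 8)
  expect_equal(sl$channel, chans)
  expect_equal(sl$n_channels, rep(2L, 6))
  best <- sl$channel[order(-sl$accuracy)][1:2]
  expect_setequal(best, c("c1", "c2"))
  # self-only adjacency equals per-channel decoding
  self_nb <- setNames(as.list(rep("", 6)), chans)
  expect_warning(sl_self <- searchlight_channels(fm, lab, self_nb, seed = 8),
                 "no neighbours")
  one <- cross_validate_10fold(
    eegreplay:::new_feature_matrix(X[, idx$channel == "c3", drop = FALSE],
                                   idx[idx$channel == "c3", ]),
    lab, seed = eegreplay::stage_seed(8, "c3"))
  expect_equal(sl_self$accuracy[3],
               confusion_accuracy(normalize_confusion(one)))
  expect_error(searchlight_channels(fm, lab, nb[1:3]), "cover")
})

test_that("frequency searchlight uses 3 neighbours except 2 at the grid ends", {
  set.seed(9)
  n <- 30
  idx <- data.frame(channel = rep(c("x", "y"), each = 5),
                    freq = rep(c(4, 5, 6, 7, 8), 2))
  X <- matrix(rnorm(n * 10), n, 10)
  lab <- rep(c("a", "b", "c"), each = 10)
  X[lab == "a", idx$freq <= 5] <- X[lab == "a", idx$freq <= 5] + 4
  X[lab == "b", idx$freq == 4] <- X[lab == "b", idx$freq == 4] - 4
  fm <- eegreplay:::new_feature_matrix(X, idx)
  sl <- searchlight_frequencies(fm, lab, seed = 10)
  expect_equal(sl$freq, c(4, 5, 6, 7, 8))
  expect_equal(sl$n_features, c(4, 6, 6, 6, 4))  # 2 channels x (2 or 3 freqs)
  expect_gt(sl$accuracy[1], sl$accuracy[5])
})

test_that("decoding timecourse reports evidence proportions that sum to one", {
  fx <- signal_fixture()
  pr <- fx$preps[[1]]
  tc <- decode_timecourse(pr$decoder, pr$ret_tfr)
  expect_length(tc$times, 85)
  tb <- tc$table
  comp_rows <- tb$condition %in% c("AB", "AC")
  expect_true(all(abs(tb$ev_target[comp_rows] + tb$ev_comp[comp_rows] +
                        tb$ev_other[comp_rows] - 1) < 1e-9))
  expect_true(all(is.na(tb$ev_comp[tb$condition == "DE"])))
  expect_true(all(abs(tb$ev_target[!comp_rows] + tb$ev_other[!comp_rows] - 1)
                  < 1e-9))
  # accuracy is the target-evidence percentage
  expect_equal(tb$acc, 100 * tb$ev_target)
  # feature-space mismatch is caught
  bad <- pr$ret_tfr
  bad$power <- bad$power[, 1:3, , , drop = FALSE]
  bad$channel_names <- bad$channel_names[1:3]
  expect_error(decode_timecourse(pr$decoder, bad), "mismatch")
})

test_that("smoothing is the centred shrinking-edge moving average", {
  x <- c(1, rep(0, 8))
  expect_equal(moving_average(x, 3), c(1 / 2, 1 / 3, rep(0, 7)))
  imp <- rep(0, 9); imp[5] <- 1
  expect_equal(moving_average(imp, 3)[4:6], rep(1 / 3, 3))
  set.seed(11)
  r <- rnorm(20)
  brute <- vapply(1:20, function(i) mean(r[max(1, i - 1):min(20, i + 1)]), 0)
  expect_equal(moving_average(r, 3), brute)
  expect_equal(moving_average(rep(2, 10), 5), rep(2, 10))

  fx <- signal_fixture()
  tc <- decode_timecourse(fx$preps[[1]]$decoder, fx$preps[[1]]$ret_tfr)
  sm <- smooth_timecourse(tc, 0.1)
  expect_true(sm$smoothed)
  de <- tc$table$condition == "DE" & tc$table$outcome == "all"
  expect_equal(sm$table$acc[de], moving_average(tc$table$acc[de], 3))
  expect_error(smooth_timecourse(tc, 0.01), "smaller than the bin step")
})
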