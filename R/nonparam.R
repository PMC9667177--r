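## Label-shuffle permutation machinery: empirical null distributions of group
## t statistics, percentile-of-t thresholds, Monte-Carlo FDR corroboration,
## and Bonferroni thresholds for searchlight maps.

#' Vectorised one-sample group t against a reference value
#'
#' @param X matrix `subjects x bins` (a vector is treated as one bin).
#' @param mu reference value (default the 33.3% chance level).
#' @return list with `t`, `mean`, `sd`, `df`, `n`.
#' @export
group_t <- function(X, mu = chance_level()) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  # subjects with no data for an outcome contribute NA rows and are dropped
  # column-wise
  n <- colSums(!is.na(X))
  m <- colMeans(X, na.rm = TRUE)
  s <- sqrt(pmax(colSums(X^2, na.rm = TRUE) - n * m^2, 0) / (n - 1))
  tv <- (m - mu) / (s / sqrt(n))
  # zero across-subject variance: 0 at the reference, else a finite sentinel
  # larger than any realistic t (keeps percentile machinery well defined)
  deg <- !is.na(s) & s == 0
  tv[deg] <- sign(m[deg] - mu) * 1e6
  list(t = tv, mean = m, sd = s, df = max(n) - 1, n = n)
}

#' Prepare one subject for decoding and permutation analysis
#'
#' Runs the fixed per-subject pipeline once — linked-mastoid re-reference,
#' whole-epoch baseline, Morlet TFR of both phases, movie-window encoding
#' features, across-trial normalisation frozen on the full encoding set, and
#' the normalised single-bin retrieval features — and precomputes the Gram
#' matrices that let label-shuffle iterations re-train the decoder for the
#' cost of a dual solve.
#'
#' @param subject one element of a cohort's `subjects` list (fields
#'   `encoding`, `retrieval`).
#' @param freqs,time_step,width TFR parameters.
#' @param enc_window encoding feature window in seconds (the movie span).
#' @param ret_times retrieval bin grid (default 85 bins, -0.2..4 s).
#' @param C decoder regularisation.
#' @return a `subject_prep` (internal structure consumed by the group-level
#'   functions; also carries the observed `decoder`).
#' @export
prepare_decoding <- function(subject, freqs = default_freqs(),
                             time_step = 0.05, width = 5,
                             enc_window = c(0, 6),
                             ret_times = seq(-0.2, 4, by = 0.05), C = 1) {
  pre <- function(ep) baseline_epoch_mean(rereference_linked_mastoids(ep))
  enc <- pre(subject$encoding)
  ret <- pre(subject$retrieval)
  enc_tfr <- morlet_tfr(enc, freqs, time_step, width)
  ret_tfr <- morlet_tfr(ret, freqs, time_step, width)
  enc_feat <- window_average_features(enc_tfr, enc_window[1], enc_window[2])
  labels <- enc$metadata$context
  decoder <- train_ova_linear(enc_feat, labels, C = C)
  X <- apply_normalization(enc_feat, decoder$norm)$values
  feats <- lapply(ret_times, function(t) bin_features(ret_tfr, t))
  Xbins <- apply_normalization(
    new_feature_matrix(do.call(rbind, lapply(feats, `[[`, "values")),
                       feats[[1]]$feature_index),
    decoder$norm)$values
  prep <- structure(list(enc_feat = enc_feat, enc_labels = labels,
                         classes = decoder$classes, decoder = decoder,
                         K = tcrossprod(X), Kbt = Xbins %*% t(X),
                         ret_tfr = ret_tfr, ret_md = ret$metadata,
                         times = ret_times, C = C),
                    class = "subject_prep")
  prep$obs_pred <- prep_predict(prep, labels)
  prep
}

# per-trial predicted class indices (trials x bins) for arbitrary encoding
# labels, re-training the three scorers on the precomputed Gram
prep_predict <- function(prep, labels) {
  fits <- ova_fit_gram(prep$K, labels, prep$classes, prep$C)
  idx <- ova_predict_idx(ova_decision(prep$Kbt, fits))
  matrix(idx, nrow(prep$ret_md), length(prep$times))
}

# smoothed per-bin accuracy (%) of predictions for one condition/outcome
prep_accuracy <- function(prep, pred, condition, outcome = "success",
                          smooth_k = 3L, against = "target") {
  md <- prep$ret_md
  sel <- md$condition == condition &
    switch(outcome, all = TRUE, success = md$success, fail = !md$success)
  if (!any(sel)) return(rep(NA_real_, length(prep$times)))
  ref <- switch(against, target = md$target_context,
                competitor = md$competitor_context)[sel]
  ref_idx <- match(ref, prep$classes)
  acc <- 100 * colMeans(pred[sel, , drop = FALSE] == ref_idx)
  moving_average(acc, smooth_k)
}

#' Observed group decoding timecourse
#'
#' Per-subject smoothed accuracy (or competitor-evidence) timecourses under
#' the true encoding labels, for one condition and outcome, plus the group t
#' against chance per bin.
#'
#' @param preps list of [prepare_decoding()] outputs.
#' @param condition `"AB"`, `"AC"` or `"DE"`.
#' @param outcome `"all"`, `"success"` or `"fail"`.
#' @param smooth_window smoothing window in seconds.
#' @param against score predictions against the `"target"` or `"competitor"`
#'   context.
#' @return list with `acc` (`subjects x bins`, %), `t` (per bin), `times`.
#' @export
observed_timecourse <- function(preps, condition, outcome = "success",
                                smooth_window = 0.1, against = "target") {
  k <- smoothing_bins(smooth_window, diff(preps[[1]]$times[1:2]))
  acc <- t(vapply(preps, function(p) {
    pred <- p$obs_pred %||% prep_predict(p, p$enc_labels)
    prep_accuracy(p, pred, condition, outcome, k, against)
  }, numeric(length(preps[[1]]$times))))
  list(acc = acc, t = group_t(acc)$t, times = preps[[1]]$times)
}

#' Label-shuffle null distribution for the retrieval timecourse
#'
#' For each iteration, the encoding context labels are shuffled within
#' subject, the one-vs-all decoder is re-trained on the shuffled labels, the
#' retrieval bins are re-decoded, and the group t against chance is computed
#' per bin from the smoothed per-subject accuracies. The returned per-bin t
#' samples form the empirical null; the per-subject accuracy array is kept so
#' leave-one-subject-out folds can rebuild their own nulls without re-running
#' the pipeline.
#'
#' @inheritParams observed_timecourse
#' @param n_iter number of shuffle iterations (>= 50; 1000 at full scale).
#' @param seed integer seed.
#' @return a `null_distribution`: `t` (`iterations x bins`), `acc`
#'   (`iterations x subjects x bins`), `times`, `n_iter`, `chance`.
#' @export
shuffle_null_timecourse <- function(preps, condition, outcome = "success",
                                    n_iter = 1000, seed = 1L,
                                    smooth_window = 0.1, against = "target") {
  stopifnot(length(preps) >= 2, n_iter >= 50)
  nb <- length(preps[[1]]$times)
  k <- smoothing_bins(smooth_window, diff(preps[[1]]$times[1:2]))
  acc <- array(NA_real_, c(n_iter, length(preps), nb))
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      for (s in seq_along(preps)) {
        p <- preps[[s]]
        lab <- sample(p$enc_labels)
        pred <- tryCatch(prep_predict(p, lab), error = function(e)
          stop("null pipeline failed at iteration ", it, ", subject ", s,
               ": ", conditionMessage(e)))
        acc[it, s, ] <- prep_accuracy(p, pred, condition, outcome, k, against)
      }
    }
  })
  tmat <- t(apply(acc, 1, function(a) group_t(a)$t))
  structure(list(t = tmat, acc = acc, times = preps[[1]]$times,
                 n_iter = n_iter, chance = chance_level()),
            class = "null_distribution")
}

#' Label-shuffle null for encoding cross-validation accuracy
#'
#' Re-runs the full 10-fold cross-validation per subject with context labels
#' shuffled, once per iteration; yields the empirical chance distribution of
#' encoding accuracy.
#'
#' @param preps list of [prepare_decoding()] outputs.
#' @param n_iter iterations (100 at full scale).
#' @param seed integer seed.
#' @param k folds.
#' @return matrix `iterations x subjects` of accuracies (%).
#' @export
shuffle_null_encoding <- function(preps, n_iter = 100, seed = 1L, k = 10) {
  stopifnot(n_iter >= 1)
  out <- matrix(NA_real_, n_iter, length(preps))
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      for (s in seq_along(preps)) {
        p <- preps[[s]]
        conf <- cross_validate_10fold(p$enc_feat, sample(p$enc_labels),
                                      C = p$C, k = k,
                                      seed = sample.int(2^31 - 1, 1))
        out[it, s] <- confusion_accuracy(normalize_confusion(conf))
      }
    }
  })
  out
}

#' Percentile-of-t significance thresholds
#'
#' The empirical `100 * alpha / 2` and `100 * (1 - alpha / 2)` percentiles of
#' the null t samples (linear-interpolation percentile convention,
#' `stats::quantile` type 7), per bin.
#'
#' @param null a `null_distribution`, or a matrix/vector of null t samples
#'   (`iterations x bins`).
#' @param alpha two-tailed significance level (default 0.05).
#' @return data.frame with `lo` and `hi` thresholds per bin.
#' @export
percentile_threshold <- function(null, alpha = 0.05) {
  tm <- if (inherits(null, "null_distribution")) null$t else null
  if (is.null(dim(tm))) tm <- matrix(tm, ncol = 1)
  if (nrow(tm) < 40) stop("need at least 40 null samples")
  data.frame(lo = apply(tm, 2, quantile, probs = alpha / 2, names = FALSE),
             hi = apply(tm, 2, quantile, probs = 1 - alpha / 2,
                        names = FALSE))
}

#' Monte-Carlo FDR-corrected permutation p-values
#'
#' Per bin, the two-tailed permutation p-value
#' `(1 + #null |t| >= |t_obs|) / (1 + n_iter)` (per-bin null by default, or
#' the null pooled over bins), followed by Benjamini-Hochberg step-up across
#' bins.
#'
#' @param observed_t numeric vector of observed group t per bin.
#' @param null a `null_distribution` or null t matrix on the same bin grid.
#' @param pooled use the null pooled across bins.
#' @return data.frame with `p_perm` and BH-adjusted `p_fdr` per bin.
#' @export
fdr_monte_carlo <- function(observed_t, null, pooled = FALSE) {
  tm <- if (inherits(null, "null_distribution")) null$t else null
  if (is.null(dim(tm))) tm <- matrix(tm, ncol = 1)
  if (ncol(tm) != length(observed_t) && !pooled)
    stop("null and observed bin grids differ")
  n_iter <- nrow(tm)
  p <- if (pooled) {
    pool <- abs(as.vector(tm))
    vapply(observed_t, function(t0) (1 + sum(pool >= abs(t0))) /
             (1 + length(pool)), 0)
  } else {
    vapply(seq_along(observed_t), function(b)
      (1 + sum(abs(tm[, b]) >= abs(observed_t[b]))) / (1 + n_iter), 0)
  }
  data.frame(p_perm = p, p_fdr = p.adjust(p, method = "BH"))
}

#' Per-bin significance under the percentile rule, FDR, and both
#'
#' Combines the percentile-of-t rule with the Monte-Carlo FDR corroboration;
#' `sig_joint` marks bins significant under both procedures (the reporting
#' rule), and is by construction a subset of each.
#'
#' @param observed an [observed_timecourse()] result (or a list with `t` and
#'   `times`).
#' @param null a `null_distribution` on the same bin grid.
#' @param alpha two-tailed level for both procedures (default 0.05).
#' @param pooled pooled-null variant for the percentile thresholds.
#' @param fdr_pooled pooled-null variant for the Monte-Carlo FDR p-values
#'   (defaults to `pooled`); at reduced iteration counts the pooled variant
#'   is the one whose p resolution can clear the step-up line.
#' @return a `significance_mask` data.frame: `time`, `t`, `lo`, `hi`,
#'   `sig_percentile`, `p_perm`, `p_fdr`, `sig_fdr`, `sig_joint`.
#' @export
significant_bins <- function(observed, null, alpha = 0.05, pooled = FALSE,
                             fdr_pooled = pooled) {
  if (!identical(length(observed$t), ncol(null$t)))
    stop("observed and null bin grids differ")
  if (!is.null(observed$times) && !is.null(null$times) &&
      !isTRUE(all.equal(observed$times, null$times)))
    stop("observed and null bin grids differ")
  thr <- if (pooled) {
    one <- percentile_threshold(as.vector(null$t), alpha)
    data.frame(lo = rep(one$lo, length(observed$t)),
               hi = rep(one$hi, length(observed$t)))
  } else percentile_threshold(null, alpha)
  fdr <- fdr_monte_carlo(observed$t, null, pooled = fdr_pooled)
  out <- data.frame(time = null$times, t = observed$t, lo = thr$lo,
                    hi = thr$hi,
                    sig_percentile = observed$t > thr$hi | observed$t < thr$lo,
                    p_perm = fdr$p_perm, p_fdr = fdr$p_fdr,
                    sig_fdr = fdr$p_fdr < alpha)
  out$sig_joint <- out$sig_percentile & out$sig_fdr
  class(out) <- c("significance_mask", "data.frame")
  out
}

#' Bonferroni-thresholded searchlight significance
#'
#' Per map cell, a one-sample t of subject accuracies against the 33.3%
#' chance level; a cell is significant when its two-tailed p falls below
#' `alpha / m` (0.05/42 = 0.0012 for the frequency map, 0.05/60 = 0.0008 for
#' the channel map at full scale).
#'
#' @param acc matrix `subjects x cells` of searchlight accuracies (%).
#' @param m number of comparisons; must equal the number of cells.
#' @param alpha familywise level before correction.
#' @return data.frame with `t`, `p`, the corrected `threshold`, and
#'   `significant` per cell.
#' @export
bonferroni_searchlight <- function(acc, m = ncol(acc), alpha = 0.05) {
  stopifnot(m >= 1)
  if (m != ncol(acc))
    stop("m (", m, ") does not match the map size (", ncol(acc), ")")
  g <- group_t(acc)
  p <- 2 * pt(abs(g$t), df = g$df, lower.tail = FALSE)
  data.frame(cell = colnames(acc) %||% seq_len(ncol(acc)), t = g$t, p = p,
             threshold = alpha / m, significant = p < alpha / m,
             row.names = NULL)
}

#' Encoding-phase significance against the shuffle null
#'
#' Observed group t of per-subject encoding accuracies against chance,
#' thresholded by the percentiles of the null distribution of the same group
#' t computed within each shuffle iteration.
#'
#' @param acc numeric vector of per-subject encoding accuracies (%).
#' @param null_acc matrix `iterations x subjects` from
#'   [shuffle_null_encoding()].
#' @param alpha two-tailed level.
#' @return one-row data.frame: observed `t`, null `mean_null_acc`,
#'   thresholds, `significant`.
#' @export
encoding_significance <- function(acc, null_acc, alpha = 0.05) {
  obs <- group_t(matrix(acc, ncol = 1))$t
  null_t <- apply(null_acc, 1, function(a) group_t(matrix(a, ncol = 1))$t)
  thr <- percentile_threshold(matrix(null_t, ncol = 1), alpha)
  data.frame(t = obs, mean_null_acc = mean(null_acc), lo = thr$lo,
             hi = thr$hi, significant = obs > thr$hi | obs < thr$lo)
}
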