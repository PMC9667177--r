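#' Complex Morlet time-frequency decomposition
#'
#' Power of the complex Morlet wavelet transform on every trial and channel:
#' the wavelet at centre frequency f has a Gaussian envelope with
#' `sigma_t = width / (2 * pi * f)` (so `width` cycles fit the envelope), is
#' L2-normalised, and power is the squared magnitude of the convolution.
#' Output bins sit on the absolute `time_step` grid inside the epoch; bins
#' where the (truncated, +/- 4 sigma_t) wavelet overruns the epoch are marked
#' invalid per frequency.
#'
#' @param x an [epochs()] object.
#' @param freqs frequency grid in Hz (default 4..45, step 1).
#' @param time_step output bin spacing in seconds (default 0.05); must be a
#'   whole number of samples.
#' @param width wavelet width in cycles (default 5).
#' @return a `tfr_stack`: list with `power` (array `trials x channels x
#'   frequencies x bins`), `freqs`, `times`, `valid` (`frequencies x bins`
#'   logical), `fs`, `channel_names`, `metadata`.
#' @export
morlet_tfr <- function(x, freqs = default_freqs(), time_step = 0.05,
                       width = 5) {
  stopifnot(inherits(x, "eeg_epochs"), all(freqs > 0), width >= 1,
            all(diff(freqs) > 0))
  stride <- time_step * x$fs
  if (abs(stride - round(stride)) > 1e-9)
    stop("time_step must be a whole number of samples at fs = ", x$fs)
  if (max(freqs) > x$fs / 2) stop("frequency grid exceeds Nyquist")
  d <- dim(x$data)
  tt <- epoch_times(x)
  # bins on the absolute time_step grid
  bt <- seq(ceiling(tt[1] / time_step - 1e-9),
            floor(tt[length(tt)] / time_step + 1e-9)) * time_step
  bin_idx <- round((bt - x$t0) * x$fs)  # 0-based sample indices

  sig <- matrix(aperm(x$data, c(3, 1, 2)), d[3], d[1] * d[2])
  res <- .morlet_power_cpp(sig, as.numeric(freqs), x$fs, width,
                           as.integer(bin_idx))
  # [bins x freqs x (trial, channel)] -> trials x channels x freqs x bins
  pw <- aperm(array(res$power, c(length(bt), length(freqs), d[1], d[2])),
              c(3, 4, 2, 1))
  margin <- res$halflen / x$fs
  valid <- t(vapply(seq_along(freqs), function(k) {
    bt >= tt[1] + margin[k] - 1e-9 & bt <= tt[length(tt)] - margin[k] + 1e-9
  }, logical(length(bt))))
  structure(list(power = pw, freqs = as.numeric(freqs), times = bt,
                 valid = valid, fs = x$fs,
                 channel_names = x$channel_names, metadata = x$metadata),
            class = "tfr_stack")
}

#' @export
print.tfr_stack <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tfr_stack> %d trials x %d channels x %d freqs x %d bins (%g..%g s)\n",
              d[1], d[2], d[3], d[4], min(x$times), max(x$times)))
  invisible(x)
}

# channel-major (channel varies slowest, frequency fastest) feature index
feature_index <- function(tfr) {
  data.frame(channel = rep(tfr$channel_names, each = length(tfr$freqs)),
             freq = rep(tfr$freqs, length(tfr$channel_names)),
             stringsAsFactors = FALSE)
}

new_feature_matrix <- function(values, index, normalization = "raw") {
  stopifnot(ncol(values) == nrow(index))
  structure(list(values = values, feature_index = index,
                 normalization = normalization),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (is.character(x$normalization)) x$normalization else "z-scored"))
  invisible(x)
}

#' Time-averaged (channel, frequency) features
#'
#' Mean power over the bins inside `[t0, t1]` for every trial, flattened to a
#' `trials x (channels * frequencies)` feature matrix in channel-major order
#' (all frequencies of channel 1, then channel 2, ...). Bins marked invalid
#' at any requested frequency are refused.
#'
#' @param tfr a `tfr_stack`.
#' @param t0,t1 window limits in seconds (inclusive).
#' @return a `feature_matrix`.
#' @export
window_average_features <- function(tfr, t0, t1) {
  sel <- which(tfr$times >= t0 - 1e-9 & tfr$times <= t1 + 1e-9)
  if (length(sel) == 0) stop("empty feature window")
  if (!all(tfr$valid[, sel]))
    stop("feature window [", t0, ", ", t1, "] includes invalid edge bins")
  avg <- rowMeans(tfr$power[, , , sel, drop = FALSE], dims = 3)
  d <- dim(avg)
  vals <- matrix(aperm(avg, c(1, 3, 2)), d[1], d[2] * d[3])
  new_feature_matrix(vals, feature_index(tfr))
}

#' Single-bin features
#'
#' The `trials x (channels * frequencies)` slice at one bin time, with the
#' same feature order as [window_average_features()].
#'
#' @param tfr a `tfr_stack`.
#' @param t bin time in seconds; must lie on the bin grid.
#' @return a `feature_matrix`.
#' @export
bin_features <- function(tfr, t) {
  b <- which(abs(tfr$times - t) < 1e-9)
  if (length(b) != 1) stop("t = ", t, " is not on the bin grid")
  sl <- tfr$power[, , , b, drop = FALSE]
  d <- dim(sl)
  vals <- matrix(aperm(sl, c(1, 3, 2, 4)), d[1], d[2] * d[3])
  new_feature_matrix(vals, feature_index(tfr))
}

#' Across-trial feature normalisation
#'
#' Z-scores every (channel, frequency) feature using mean and sample SD
#' computed on the training matrix only; the frozen statistics are applied
#' unchanged to any further matrices (test folds, retrieval bins), keeping
#' cross-validation and cross-phase application free of leakage. Features
#' with near-zero training SD are set to zero everywhere. With
#' `pooled = TRUE` the statistics are instead computed on all matrices
#' stacked together (the literal pooled reading; not used by default).
#'
#' @param train a `feature_matrix` with at least two trials.
#' @param others optional list of `feature_matrix` objects to transform with
#'   the training statistics.
#' @param pooled logical; pool all matrices when computing the statistics.
#' @param eps SD floor below which a feature is zeroed.
#' @return list with `train`, `others` (both normalised), and the `stats`
#'   (`mean`, `sd`, `dropped` feature count).
#' @export
normalize_across_trials <- function(train, others = list(), pooled = FALSE,
                                    eps = 1e-12) {
  stopifnot(inherits(train, "feature_matrix"))
  if (nrow(train$values) < 2) stop("need >= 2 training trials to normalise")
  basis <- if (pooled)
    do.call(rbind, c(list(train$values), lapply(others, `[[`, "values")))
  else train$values
  mu <- colMeans(basis)
  sdv <- apply(basis, 2, sd)
  dead <- sdv < eps
  sdv[dead] <- 1
  stats <- list(mean = mu, sd = sdv, dead = dead, dropped = sum(dead))
  list(train = apply_normalization(train, stats),
       others = lapply(others, apply_normalization, stats = stats),
       stats = stats)
}

# apply frozen statistics to a raw feature matrix
apply_normalization <- function(fm, stats) {
  v <- sweep(sweep(fm$values, 2, stats$mean), 2, stats$sd, "/")
  if (any(stats$dead)) v[, stats$dead] <- 0
  new_feature_matrix(v, fm$feature_index, normalization = stats)
}

#' Log-transform and baseline-correct a TFR stack
#'
#' For the univariate analysis: per trial, channel and frequency, log power
#' minus the mean log power over the baseline window. Zero power cells are
#' floored at `eps` with a warning.
#'
#' @param tfr a `tfr_stack`.
#' @param base_window two seconds, e.g. `c(-1, 0)`.
#' @param eps floor for zero power.
#' @return a `tfr_stack` of log-baseline-corrected values (may be negative).
#' @export
log_baseline_tfr <- function(tfr, base_window = c(-1, 0), eps = 1e-20) {
  sel <- which(tfr$times >= base_window[1] - 1e-9 &
               tfr$times <= base_window[2] + 1e-9)
  if (length(sel) == 0) stop("empty baseline window")
  p <- tfr$power
  if (any(p < eps)) {
    warning("zero power cells floored at eps")
    p[p < eps] <- eps
  }
  lp <- log(p)
  base <- rowMeans(lp[, , , sel, drop = FALSE], dims = 3)
  tfr$power <- lp - as.vector(base)  # recycles over the bin dimension
  tfr
}
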