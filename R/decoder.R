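## One-vs-all linear-margin context classification.
##
## All fitting goes through a binary C-SVC dual solver on a precomputed Gram
## matrix (src/svm.cpp), so permutation loops can reuse the Gram across label
## shuffles and pay only for the (cheap) dual optimisation.

# fit the three one-vs-rest binary scorers on a Gram matrix
ova_fit_gram <- function(K, labels, classes, C) {
  lapply(classes, function(cl) {
    y <- ifelse(labels == cl, 1, -1)
    if (all(y == 1) || all(y == -1))
      stop("degenerate labels: class ", cl, " vs rest has one side empty")
    .svc_fit_cpp(K, y, C)
  })
}

# decision values (trials x classes) from cross-Gram K_new_train
ova_decision <- function(Knt, fits) {
  AY <- do.call(cbind, lapply(fits, `[[`, "alpha_y"))
  sweep(Knt %*% AY, 2, vapply(fits, `[[`, 0, "b"), "+")
}

# argmax with deterministic tie-break on the lowest class index
ova_predict_idx <- function(dec) max.col(dec, ties.method = "first")

#' Train a one-vs-all linear context decoder
#'
#' Fits, for each of the three context classes, a max-margin linear separator
#' of that class against the rest on across-trial normalised features
#' (statistics computed here and frozen into the decoder). Prediction is the
#' argmax of the three decision values; exact ties go to the lowest class
#' index (class order = sorted unique labels, or the order of a factor's
#' levels).
#'
#' @param features a raw `feature_matrix` of encoding trials.
#' @param labels context label per trial (3 classes).
#' @param C soft-margin regularisation constant (default 1).
#' @return a `trained_decoder`: per-class weight vectors `W` (features x
#'   classes), biases `b`, the class order, frozen normalisation statistics,
#'   and `C`.
#' @export
train_ova_linear <- function(features, labels, C = 1) {
  stopifnot(inherits(features, "feature_matrix"))
  classes <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  labels <- as.character(labels)
  if (length(classes) < 2) stop("need at least two classes")
  if (min(table(labels)) < 2) stop("need >= 2 trials per class")
  if (!all(is.finite(features$values))) stop("non-finite feature values")
  nrm <- normalize_across_trials(features)
  X <- nrm$train$values
  K <- tcrossprod(X)
  fits <- ova_fit_gram(K, labels, classes, C)
  W <- vapply(fits, function(f) as.numeric(crossprod(X, f$alpha_y)),
              numeric(ncol(X)))
  structure(list(W = W, b = vapply(fits, `[[`, 0, "b"), classes = classes,
                 norm = nrm$stats, C = C,
                 feature_index = features$feature_index),
            class = "trained_decoder")
}

#' @export
print.trained_decoder <- function(x, ...) {
  cat(sprintf("<trained_decoder> %d features, classes: %s (C = %g)\n",
              nrow(x$W), paste(x$classes, collapse = ", "), x$C))
  invisible(x)
}

#' Predict contexts with a trained decoder
#'
#' @param object a `trained_decoder`.
#' @param features a raw `feature_matrix` on the same feature space (the
#'   decoder's frozen normalisation is applied here).
#' @param type `"class"` or `"decision"`.
#' @param ... unused.
#' @return predicted class labels, or the trials x classes decision matrix.
#' @export
predict.trained_decoder <- function(object, features, type = "class", ...) {
  if (ncol(features$values) != nrow(object$W))
    stop("feature-space mismatch: decoder has ", nrow(object$W),
         " features, data has ", ncol(features$values))
  X <- apply_normalization(features, object$norm)$values
  dec <- sweep(X %*% object$W, 2, object$b, "+")
  colnames(dec) <- object$classes
  if (type == "decision") return(dec)
  object$classes[ova_predict_idx(dec)]
}

#' Stratification-free k-fold cross-validated confusion counts
#'
#' Randomly partitions the trials into `k` subsets of sizes differing by at
#' most one; each fold is predicted once by a decoder trained on the rest,
#' with feature normalisation recomputed on each training fold and applied
#' frozen to the held-out fold. Counts are accumulated over folds.
#'
#' @param features raw `feature_matrix`.
#' @param labels context per trial.
#' @param C regularisation constant.
#' @param k number of folds (default 10).
#' @param seed integer seed for the partition.
#' @return a `confusion_matrix` of counts (true x predicted).
#' @export
cross_validate_10fold <- function(features, labels, C = 1, k = 10,
                                  seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  n <- nrow(features$values)
  if (n < k) stop("fewer trials (", n, ") than folds (", k, ")")
  fold <- with_seed(seed, rep_len(seq_len(k), n)[sample.int(n)])
  counts <- matrix(0L, length(classes), length(classes),
                   dimnames = list(true = classes, predicted = classes))
  X <- features$values
  for (f in seq_len(k)) {
    te <- fold == f
    nrm <- normalize_across_trials(
      new_feature_matrix(X[!te, , drop = FALSE], features$feature_index),
      list(new_feature_matrix(X[te, , drop = FALSE], features$feature_index)))
    Xtr <- nrm$train$values
    Xte <- nrm$others[[1]]$values
    fits <- ova_fit_gram(tcrossprod(Xtr), labels[!te], classes, C)
    pred <- classes[ova_predict_idx(ova_decision(Xte %*% t(Xtr), fits))]
    tab <- table(factor(labels[te], classes), factor(pred, classes))
    counts <- counts + as.matrix(tab)
  }
  structure(list(counts = counts, normalized = FALSE, classes = classes),
            class = "confusion_matrix")
}

#' Row-normalise a confusion matrix
#'
#' Divides every element by its row sum so each row (true class) sums to one.
#'
#' @param conf a `confusion_matrix` of counts.
#' @return a `confusion_matrix` of row proportions.
#' @export
normalize_confusion <- function(conf) {
  stopifnot(inherits(conf, "confusion_matrix"))
  rs <- rowSums(conf$counts)
  if (any(rs == 0)) stop("empty row in confusion matrix")
  structure(list(counts = conf$counts / rs, normalized = TRUE,
                 classes = conf$classes, n_per_row = rs),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %s\n",
              if (x$normalized) "row proportions" else "counts"))
  print(round(x$counts, 3))
  invisible(x)
}

#' Decoding accuracy from a confusion matrix, in percent
#'
#' 100 times the mean of the diagonal of the row-normalised matrix.
#'
#' @param conf a normalised `confusion_matrix` (counts are refused).
#' @return accuracy in percent.
#' @export
confusion_accuracy <- function(conf) {
  stopifnot(inherits(conf, "confusion_matrix"))
  if (!conf$normalized) stop("normalise the confusion matrix first")
  100 * mean(diag(conf$counts))
}

#' Channel searchlight decoding map
#'
#' Reruns the cross-validated classification once per channel using only that
#' channel and its montage neighbours (all frequencies), allocating the
#' accuracy to the centre channel. A channel without neighbours runs alone,
#' with a warning.
#'
#' @param features raw `feature_matrix` (channel-major index).
#' @param labels context per trial.
#' @param neighbors named neighbour list ([channel_neighbors()]).
#' @param C,k,seed passed to [cross_validate_10fold()].
#' @return data.frame with `channel`, `accuracy` (%), `n_channels`.
#' @export
searchlight_channels <- function(features, labels, neighbors, C = 1, k = 10,
                                 seed = 1L) {
  chans <- unique(features$feature_index$channel)
  if (!all(chans %in% names(neighbors)))
    stop("adjacency does not cover all channels")
  out <- lapply(chans, function(ch) {
    nb <- intersect(neighbors[[ch]], chans)
    if (length(nb) == 0)
      warning("channel ", ch, " has no neighbours; running alone")
    cols <- features$feature_index$channel %in% c(ch, nb)
    sub <- new_feature_matrix(features$values[, cols, drop = FALSE],
                              features$feature_index[cols, ])
    conf <- cross_validate_10fold(sub, labels, C = C, k = k,
                                  seed = stage_seed(seed, ch))
    data.frame(channel = ch,
               accuracy = confusion_accuracy(normalize_confusion(conf)),
               n_channels = length(nb) + 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Frequency searchlight decoding map
#'
#' Reruns the classification once per frequency using the centre frequency
#' and its immediate grid neighbours (three frequencies, two at the grid
#' ends), over all channels.
#'
#' @inheritParams searchlight_channels
#' @return data.frame with `freq`, `accuracy` (%), `n_features`.
#' @export
searchlight_frequencies <- function(features, labels, C = 1, k = 10,
                                    seed = 1L) {
  fr <- sort(unique(features$feature_index$freq))
  if (length(fr) < 2) stop("need at least two frequencies")
  out <- lapply(seq_along(fr), function(i) {
    band <- fr[max(1, i - 1):min(length(fr), i + 1)]
    cols <- features$feature_index$freq %in% band
    sub <- new_feature_matrix(features$values[, cols, drop = FALSE],
                              features$feature_index[cols, ])
    conf <- cross_validate_10fold(sub, labels, C = C, k = k,
                                  seed = stage_seed(seed, paste0("f", fr[i])))
    data.frame(freq = fr[i],
               accuracy = confusion_accuracy(normalize_confusion(conf)),
               n_features = sum(cols), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-phase decoding timecourse
#'
#' Applies an encoding-trained decoder to every retrieval time bin (default:
#' the 85-bin grid from -0.2 to 4 s in 0.05-s steps), using the decoder's
#' frozen normalisation. Per (condition, outcome, bin) the summary records
#' the proportion of trials predicted as the target context (`ev_target`,
#' whose percentage is the accuracy with respect to the target label), as the
#' competitor context (`ev_comp`, defined for AB/AC trials), and as any other
#' context; the three proportions sum to one.
#'
#' @param decoder a `trained_decoder`.
#' @param ret_tfr retrieval-phase `tfr_stack` whose metadata carries
#'   `condition`, `target_context`, `competitor_context`, `success`.
#' @param times bin times to decode (default the 85-bin grid).
#' @return a `decoding_timecourse`: `times`, per-trial predicted-class matrix
#'   `pred`, the metadata, tidy summary `table` (columns `condition`,
#'   `outcome` in all/success/fail, `time`, `n_trials`, `acc`, `ev_target`,
#'   `ev_comp`, `ev_other`), and a `smoothed` flag.
#' @export
decode_timecourse <- function(decoder, ret_tfr,
                              times = seq(-0.2, 4, by = 0.05)) {
  md <- ret_tfr$metadata
  stopifnot(all(c("condition", "target_context", "success") %in% names(md)))
  n <- nrow(md)
  feats <- lapply(times, function(t) bin_features(ret_tfr, t))
  big <- new_feature_matrix(do.call(rbind, lapply(feats, `[[`, "values")),
                            feats[[1]]$feature_index)
  pred <- matrix(predict(decoder, big), n, length(times))
  tc <- structure(list(times = times, pred = pred, metadata = md,
                       smoothed = FALSE, classes = decoder$classes),
                  class = "decoding_timecourse")
  tc$table <- summarize_timecourse(tc)
  tc
}

# tidy per-(condition, outcome, bin) evidence table from per-trial predictions
summarize_timecourse <- function(tc) {
  md <- tc$metadata
  rows <- list()
  for (cond in sort(unique(md$condition))) {
    for (out in c("all", "success", "fail")) {
      sel <- md$condition == cond &
        switch(out, all = TRUE, success = md$success, fail = !md$success)
      if (!any(sel)) next
      p <- tc$pred[sel, , drop = FALSE]
      tg <- md$target_context[sel]
      cp <- md$competitor_context[sel]
      ev_t <- colMeans(p == tg)
      ev_c <- if (all(is.na(cp))) rep(NA_real_, length(tc$times))
              else colMeans(p == cp)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, outcome = out, time = tc$times,
        n_trials = sum(sel), acc = 100 * ev_t, ev_target = ev_t,
        ev_comp = ev_c,
        ev_other = 1 - ev_t - ifelse(is.na(ev_c), 0, ev_c),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Moving-average smoothing of a decoding timecourse
#'
#' Centred moving average (window default 0.1 s, i.e. three 0.05-s bins;
#' edges use the available bins) applied to every accuracy/evidence series in
#' the summary table, as used for display and for the group t statistics.
#'
#' @param tc a `decoding_timecourse`.
#' @param window smoothing window in seconds (>= the bin step).
#' @return the timecourse with smoothed summary series and `smoothed = TRUE`.
#' @export
smooth_timecourse <- function(tc, window = 0.1) {
  step <- diff(tc$times[1:2])
  if (window < step) stop("window smaller than the bin step")
  k <- smoothing_bins(window, step)
  tb <- tc$table
  for (grp in split(seq_len(nrow(tb)),
                    paste(tb$condition, tb$outcome))) {
    for (colname in c("acc", "ev_target", "ev_comp", "ev_other")) {
      v <- tb[[colname]][grp]
      if (!anyNA(v)) tb[[colname]][grp] <- moving_average(v, k)
    }
  }
  tc$table <- tb
  tc$smoothed <- TRUE
  tc
}
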