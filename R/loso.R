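## Leave-one-subject-out window selection and the condition/memory contrasts
## evaluated inside the selected windows.

#' Leave-one-subject-out time-bin selection
#'
#' For each left-out subject, the group t against chance is recomputed per
#' bin over the remaining subjects, thresholded by that fold's own
#' permutation null (the stored per-subject null accuracies re-aggregated
#' without the left-out subject), and the significant bins falling within
#' `reference_window` widened by `margin` on each side are selected for that
#' subject. The left-out subject's data never enter its own selection, which
#' is what protects the downstream contrasts from selection bias. An empty
#' selection falls back to the bin nearest the reference-window centre, with
#' a warning recorded.
#'
#' @param acc matrix `subjects x bins` of smoothed accuracies (%), e.g.
#'   `observed_timecourse()$acc`.
#' @param null a `null_distribution` holding the per-subject null accuracy
#'   array on the same grid.
#' @param reference_window two seconds: the group-level window being probed.
#' @param margin seconds added on both sides (default 0.2).
#' @param alpha two-tailed level for the fold thresholds.
#' @return a `loso_windows`: per-subject selected bin indices, `times`,
#'   `reference_window`, `margin`, `fallback` flags.
#' @export
loso_select <- function(acc, null, reference_window, margin = 0.2,
                        alpha = 0.05) {
  n_sub <- nrow(acc)
  if (n_sub < 3) stop("need at least 3 subjects for LOSO selection")
  times <- null$times
  stopifnot(ncol(acc) == length(times))
  lo_t <- reference_window[1] - margin - 1e-9
  hi_t <- reference_window[2] + margin + 1e-9
  in_win <- times >= lo_t & times <= hi_t
  if (!any(in_win)) stop("reference window (+ margin) misses the bin grid")
  centre <- which.min(abs(times - mean(reference_window)))
  sel <- vector("list", n_sub)
  fallback <- logical(n_sub)
  for (s in seq_len(n_sub)) {
    keep <- setdiff(seq_len(n_sub), s)
    obs_t <- group_t(acc[keep, , drop = FALSE])$t
    null_t <- t(apply(null$acc[, keep, , drop = FALSE], 1, function(a)
      group_t(a)$t))
    thr <- percentile_threshold(null_t, alpha)
    sig <- (obs_t > thr$hi | obs_t < thr$lo) & in_win
    sig[is.na(sig)] <- FALSE
    if (any(sig)) {
      sel[[s]] <- which(sig)
    } else {
      sel[[s]] <- centre
      fallback[s] <- TRUE
    }
  }
  if (any(fallback))
    warning(sum(fallback), " LOSO fold(s) had no significant bins; ",
            "fell back to the reference-window centre bin")
  structure(list(selected = sel, times = times,
                 reference_window = reference_window, margin = margin,
                 fallback = fallback),
            class = "loso_windows")
}

#' Successful-versus-unsuccessful retrieval contrast in LOSO windows
#'
#' Per subject, the mean accuracy over that subject's LOSO-selected bins is
#' extracted separately for successful and unsuccessful trials; subjects with
#' too few trials of either outcome are excluded; the remaining subjects
#' enter a two-tailed paired t-test with the paired-design Cohen's d (mean
#' difference over the SD of the differences).
#'
#' @param acc_success,acc_fail matrices `subjects x bins` of smoothed
#'   accuracies (%).
#' @param n_success,n_fail per-subject trial counts behind those series.
#' @param loso a [loso_select()] result.
#' @param min_trials exclusion threshold: a subject needs strictly more than
#'   `min_trials` trials of each outcome (default 10).
#' @return a `contrast_result` data.frame row: effect, per-condition means,
#'   t, df, p, Cohen's d, n used and n excluded.
#' @export
success_contrast <- function(acc_success, acc_fail, n_success, n_fail, loso,
                             min_trials = 10) {
  stopifnot(nrow(acc_success) == nrow(acc_fail),
            length(loso$selected) == nrow(acc_success))
  eligible <- n_success > min_trials & n_fail > min_trials
  if (sum(eligible) < 3)
    stop("fewer than 3 subjects exceed the ", min_trials, "-trial minimum")
  per_sub <- function(acc) vapply(seq_len(nrow(acc)), function(s)
    mean(acc[s, loso$selected[[s]]]), 0)
  ms <- per_sub(acc_success)[eligible]
  mf <- per_sub(acc_fail)[eligible]
  d <- ms - mf
  if (sd(d) == 0) {
    stat <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    tt <- list(statistic = stat, parameter = length(d) - 1,
               p.value = if (mean(d) == 0) 1 else 0)
    es <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
  } else {
    tt <- t.test(ms, mf, paired = TRUE)
    es <- mean(d) / sd(d)
  }
  res <- data.frame(effect = "success_vs_fail",
                    mean_success = mean(ms), mean_fail = mean(mf),
                    statistic = unname(tt$statistic), df = unname(tt$parameter),
                    p = tt$p.value,
                    effect_size = es, n = sum(eligible),
                    n_excluded = sum(!eligible), stringsAsFactors = FALSE)
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Repeated-measures ANOVA for fully within-subject factorial layouts
#'
#' Standard within-subject decomposition (each effect tested against its
#' subject-by-effect interaction) for balanced complete designs with up to
#' three within factors, via `stats::aov` with an `Error(subject/...)`
#' stratification. Reports F, degrees of freedom, p and partial eta squared
#' per main effect and interaction. All factors used here have two or three
#' levels; two-level factors need no sphericity correction, and none is
#' applied.
#'
#' @param data data.frame with columns `subject`, `value`, and 1-3 factor
#'   columns named in `factors`.
#' @param factors character vector of the within-subject factor columns.
#' @return a `contrast_result` data.frame, one row per effect.
#' @export
rm_anova <- function(data, factors) {
  stopifnot(all(c("subject", "value", factors) %in% names(data)),
            length(factors) >= 1, length(factors) <= 3)
  data$subject <- factor(data$subject)
  for (f in factors) data[[f]] <- factor(data[[f]])
  cells <- table(data[c("subject", factors)])
  if (any(cells != 1))
    stop("design must be complete and balanced with one value per cell")
  if (nlevels(data$subject) < 3) stop("need at least 3 subjects")
  rhs <- paste(factors, collapse = " * ")
  form <- stats::as.formula(
    paste0("value ~ ", rhs, " + Error(subject/(", rhs, "))"))
  fit <- aov(form, data = data)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    resid <- terms == "Residuals"
    if (!any(resid) || all(resid)) next
    ss_err <- tab[resid, "Sum Sq"]
    df_err <- tab[resid, "Df"]
    for (i in which(!resid)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[i], statistic = tab[i, "F value"],
        df1 = tab[i, "Df"], df2 = df_err, p = tab[i, "Pr(>F)"],
        effect_size = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ss_err),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' One-sample t-test against chance with Cohen's d
#'
#' @param values per-subject values (e.g. mean accuracies, %).
#' @param mu reference (default the 33.3% chance level).
#' @return a `contrast_result` data.frame row. Zero variance around a
#'   nonzero mean difference yields an infinite t, flagged in `degenerate`.
#' @export
one_sample_t <- function(values, mu = chance_level()) {
  stopifnot(length(values) >= 2)
  if (sd(values) == 0) {
    delta <- mean(values) - mu
    res <- data.frame(effect = "vs_chance", mean = mean(values),
                      statistic = if (delta == 0) 0 else Inf * sign(delta),
                      df = length(values) - 1,
                      p = if (delta == 0) 1 else 0,
                      effect_size = if (delta == 0) 0 else Inf * sign(delta),
                      n = length(values), degenerate = delta != 0)
  } else {
    tt <- t.test(values, mu = mu)
    res <- data.frame(effect = "vs_chance", mean = mean(values),
                      statistic = unname(tt$statistic),
                      df = unname(tt$parameter), p = tt$p.value,
                      effect_size = (mean(values) - mu) / sd(values),
                      n = length(values), degenerate = FALSE)
  }
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Export contrast results as a tidy delimited table
#' @param results a `contrast_result` (or rbind of several).
#' @param file output path.
#' @export
write_contrasts <- function(results, file) {
  utils::write.table(results, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
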