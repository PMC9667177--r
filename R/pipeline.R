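## End-to-end orchestration: simulate -> preprocess -> TFR -> train -> decode
## -> permutation statistics -> LOSO contrasts -> cluster univariate ->
## report, with one master seed from which every stage derives its own.

#' Pipeline run configuration
#'
#' Bundles the simulation configuration, the TFR/decoder settings, the
#' statistics settings and a master seed. Iteration counts default to
#' desk-scale values; `full_scale = TRUE` switches to the full-scale counts
#' (100 encoding / 1000 retrieval shuffle iterations, 10,000 cluster draws).
#'
#' @param sim a [sim_config()] (its seed is overridden from `seed`).
#' @param freqs,time_step,width TFR grid and wavelet width.
#' @param enc_window encoding feature window (movie span), seconds.
#' @param ret_times retrieval decoding grid (85 bins by default).
#' @param C decoder regularisation.
#' @param n_iter_encoding,n_iter_retrieval shuffle iterations.
#' @param cluster_draws cluster-test random draws.
#' @param alpha two-tailed significance level.
#' @param margin LOSO window margin, seconds.
#' @param min_trials per-outcome trial minimum for success contrasts.
#' @param fdr_pooled use the pooled-null Monte-Carlo FDR variant in the
#'   retrieval significance masks (advisable below ~1700 iterations; see the
#'   methods vignette).
#' @param smooth_window moving-average window, seconds.
#' @param do_searchlight run the channel/frequency searchlights.
#' @param full_scale use full-scale iteration counts.
#' @param out_dir optional directory for stage artifacts; re-runs with an
#'   identical configuration reuse cached stages found there.
#' @param seed master seed; stage seeds derive from it by stage name.
#' @return a `run_config` list.
#' @export
run_config <- function(sim, freqs = default_freqs(), time_step = 0.05,
                       width = 5, enc_window = c(0, 6),
                       ret_times = seq(-0.2, 4, by = 0.05), C = 1,
                       n_iter_encoding = 100, n_iter_retrieval = 100,
                       cluster_draws = 499, alpha = 0.05, margin = 0.2,
                       min_trials = 10, smooth_window = 0.1,
                       fdr_pooled = FALSE, do_searchlight = TRUE,
                       full_scale = FALSE, out_dir = NULL, seed = 1L) {
  if (full_scale) {
    n_iter_encoding <- 100
    n_iter_retrieval <- 1000
    cluster_draws <- 10000
  }
  cfg <- list(sim = sim, freqs = freqs, time_step = time_step, width = width,
              enc_window = enc_window, ret_times = ret_times, C = C,
              n_iter_encoding = n_iter_encoding,
              n_iter_retrieval = n_iter_retrieval,
              cluster_draws = cluster_draws, alpha = alpha, margin = margin,
              min_trials = min_trials, smooth_window = smooth_window,
              fdr_pooled = fdr_pooled,
              do_searchlight = do_searchlight, out_dir = out_dir,
              seed = as.integer(seed))
  cfg$sim$seed <- stage_seed(cfg$seed, "simulate")
  class(cfg) <- "run_config"
  cfg
}

# weak configuration fingerprint for stage caching and provenance
config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  s <- jsonlite::serializeJSON(cfg)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% .Machine$integer.max)
}

cache_path <- function(cfg, stage) {
  if (is.null(cfg$out_dir)) return(NULL)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(cfg$out_dir, sprintf("%s_%s.rds", stage, config_hash(cfg)))
}

with_cache <- function(cfg, stage, expr) {
  path <- cache_path(cfg, stage)
  if (!is.null(path) && file.exists(path)) return(readRDS(path))
  val <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  if (!is.null(path)) saveRDS(val, path)
  val
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort, prepares every subject, cross-validates
#' the encoding context decoder, runs the searchlights, decodes the retrieval
#' timecourses per condition, builds the shuffle nulls and significance
#' masks, runs the LOSO-selected success contrast for noncompetitive
#' retrieval and the early/late target-competitor ANOVA for competitive
#' retrieval, and runs the cluster-based univariate retrieval-success
#' contrast.
#'
#' @param cfg a [run_config()].
#' @param cohort optional pre-generated `synthetic_cohort` (otherwise
#'   simulated from `cfg$sim`).
#' @return a `run_report` list; see [summarize_run()].
#' @export
run_pipeline <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  t_start <- Sys.time()
  cohort <- cohort %||% with_cache(cfg, "simulate", generate_cohort(cfg$sim))
  preps <- with_cache(cfg, "prepare", lapply(cohort$subjects, function(su)
    prepare_decoding(su, cfg$freqs, cfg$time_step, cfg$width,
                     cfg$enc_window, cfg$ret_times, cfg$C)))
  n_sub <- length(preps)

  ## encoding: cross-validated confusion per subject, group accuracy
  encoding <- with_cache(cfg, "encoding", {
    confs <- lapply(seq_len(n_sub), function(s)
      normalize_confusion(cross_validate_10fold(
        preps[[s]]$enc_feat, preps[[s]]$enc_labels, C = cfg$C,
        seed = stage_seed(cfg$seed, paste0("cv", s)))))
    acc <- vapply(confs, confusion_accuracy, 0)
    null_acc <- shuffle_null_encoding(preps, cfg$n_iter_encoding,
                                      stage_seed(cfg$seed, "null_enc"))
    per_class <- 100 * t(vapply(confs, function(cf) diag(cf$counts),
                                numeric(length(confs[[1]]$classes))))
    colnames(per_class) <- confs[[1]]$classes
    list(confusions = confs,
         mean_confusion = Reduce(`+`, lapply(confs, `[[`, "counts")) / n_sub,
         accuracy = acc, per_class_accuracy = per_class,
         null_acc = null_acc,
         significance = encoding_significance(acc, null_acc, cfg$alpha))
  })

  searchlight <- if (cfg$do_searchlight) with_cache(cfg, "searchlight", {
    nb <- channel_neighbors(cfg$sim$montage)
    ch_maps <- lapply(seq_len(n_sub), function(s)
      searchlight_channels(preps[[s]]$enc_feat, preps[[s]]$enc_labels, nb,
                           C = cfg$C, seed = stage_seed(cfg$seed, paste0("slc", s))))
    fr_maps <- lapply(seq_len(n_sub), function(s)
      searchlight_frequencies(preps[[s]]$enc_feat, preps[[s]]$enc_labels,
                              C = cfg$C, seed = stage_seed(cfg$seed, paste0("slf", s))))
    ch_acc <- t(vapply(ch_maps, `[[`, numeric(nrow(ch_maps[[1]])), "accuracy"))
    colnames(ch_acc) <- ch_maps[[1]]$channel
    fr_acc <- t(vapply(fr_maps, `[[`, numeric(nrow(fr_maps[[1]])), "accuracy"))
    colnames(fr_acc) <- fr_maps[[1]]$freq
    list(channel_accuracy = ch_acc, freq_accuracy = fr_acc,
         channel_bonferroni = bonferroni_searchlight(ch_acc, alpha = cfg$alpha),
         freq_bonferroni = bonferroni_searchlight(fr_acc, alpha = cfg$alpha))
  }) else NULL

  ## retrieval: per condition, observed + null + significance mask
  retrieval <- with_cache(cfg, "retrieval", {
    out <- list()
    for (cond in c("DE", "AC", "AB")) {
      obs <- observed_timecourse(preps, cond, "success", cfg$smooth_window)
      null <- shuffle_null_timecourse(
        preps, cond, "success", cfg$n_iter_retrieval,
        stage_seed(cfg$seed, paste0("null_", cond)), cfg$smooth_window)
      out[[cond]] <- list(observed = obs, null = null,
                          mask = significant_bins(obs, null, cfg$alpha,
                                                  fdr_pooled = cfg$fdr_pooled))
    }
    out
  })

  ## condition/memory contrasts inside LOSO-selected windows
  contrasts <- with_cache(cfg, "contrasts", {
    sched <- cohort$ground_truth$schedule
    win_for <- function(cond, which) {
      for (ev in sched)
        if (ev$condition == cond && ev$which_context == which)
          return(ev$window)
      NULL
    }
    res <- list()
    de_win <- win_for("DE", "target") %||% c(0.9, 1.0)
    de <- retrieval$DE
    loso <- loso_select(de$observed$acc, de$null, de_win, cfg$margin,
                        cfg$alpha)
    fail <- observed_timecourse(preps, "DE", "fail", cfg$smooth_window)
    n_s <- vapply(preps, function(p)
      sum(p$ret_md$condition == "DE" & p$ret_md$success), 0)
    n_f <- vapply(preps, function(p)
      sum(p$ret_md$condition == "DE" & !p$ret_md$success), 0)
    res$de_success <- tryCatch(
      success_contrast(de$observed$acc, fail$acc, n_s, n_f, loso,
                       cfg$min_trials),
      error = function(e) {
        warning("DE success contrast skipped: ", conditionMessage(e))
        NULL
      })
    res$de_loso <- loso

    ## AC probe window: early (competitor) vs late (target) evidence by
    ## memory performance and context
    early <- win_for("AC", "competitor") %||% c(2.35, 2.45)
    late <- win_for("AC", "target") %||% c(2.5, 2.8)
    cells <- list()
    for (wname in c("early", "late")) {
      win <- if (wname == "early") early else late
      bins <- which(cfg$ret_times >= win[1] - 1e-9 &
                    cfg$ret_times <= win[2] + 1e-9)
      for (outc in c("success", "fail")) {
        for (ctx in c("target", "competitor")) {
          tc <- observed_timecourse(preps, "AC", outc, cfg$smooth_window,
                                    against = ctx)
          cells[[length(cells) + 1L]] <- data.frame(
            subject = seq_len(n_sub), time_window = wname,
            memory = outc, context = ctx,
            value = rowMeans(tc$acc[, bins, drop = FALSE]))
        }
      }
    }
    ac_cells <- do.call(rbind, cells)
    keep <- !is.na(ac_cells$value)
    complete <- names(which(tapply(keep, ac_cells$subject, all)))
    ac_cells <- ac_cells[ac_cells$subject %in% complete & keep, ]
    res$ac_anova <- tryCatch(
      rm_anova(ac_cells, c("time_window", "memory", "context")),
      error = function(e) {
        warning("AC ANOVA skipped: ", conditionMessage(e))
        NULL
      })
    res$ac_cells <- ac_cells
    res
  })

  ## univariate cluster test: successful vs unsuccessful retrieval,
  ## cue window, classification frequency range
  cluster <- with_cache(cfg, "cluster", {
    win <- c(0.3, 1.5)
    both <- vapply(preps, function(p)
      any(p$ret_md$success) && any(!p$ret_md$success), logical(1))
    tf_means <- lapply(preps[both], function(p) {
      lb <- log_baseline_tfr(p$ret_tfr, c(-1, 0))
      sel <- lb$times >= win[1] - 1e-9 & lb$times <= win[2] + 1e-9
      md <- p$ret_md
      list(success = rowMeans(aperm(lb$power[md$success, , , sel,
                                             drop = FALSE], c(2, 3, 4, 1)),
                              dims = 3),
           fail = rowMeans(aperm(lb$power[!md$success, , , sel,
                                          drop = FALSE], c(2, 3, 4, 1)),
                           dims = 3),
           times = lb$times[sel])
    })
    dims <- dim(tf_means[[1]]$success)
    stack <- function(which) {
      arr <- array(0, c(length(tf_means), dims))
      for (s in seq_along(tf_means)) arr[s, , , ] <- tf_means[[s]][[which]]
      arr
    }
    nb <- channel_neighbors(cfg$sim$montage)
    cluster_permutation_p(stack("success"), stack("fail"), nb,
                          n_draws = cfg$cluster_draws, alpha = cfg$alpha,
                          seed = stage_seed(cfg$seed, "cluster"),
                          channel_names = preps[[1]]$ret_tfr$channel_names,
                          freqs = cfg$freqs, times = tf_means[[1]]$times)
  })

  report <- structure(list(
    encoding = encoding, searchlight = searchlight, retrieval = retrieval,
    contrasts = contrasts, cluster = cluster,
    provenance = list(config = cfg, config_hash = config_hash(cfg),
                      seed = cfg$seed, n_subjects = n_sub,
                      package_version = as.character(utils::packageVersion("eegreplay")),
                      started = t_start, finished = Sys.time())),
    class = "run_report")
  report
}

#' Summarise a pipeline run
#'
#' Prints the headline numbers (encoding accuracy and its empirical chance,
#' significant retrieval bins per condition, LOSO contrast, ANOVA table,
#' clusters) and returns, invisibly, a list of ggplot objects: the decoding
#' timecourses with significant bins highlighted, the mean confusion matrix,
#' and the searchlight maps.
#'
#' @param report a `run_report`.
#' @return invisible list of plots.
#' @export
summarize_run <- function(report) {
  stopifnot(inherits(report, "run_report"))
  enc <- report$encoding
  tshow <- if (abs(enc$significance$t) >= 1e5) "at ceiling"
           else sprintf("t = %.2f", enc$significance$t)
  cat(sprintf("Encoding decoding accuracy: %.1f%% (empirical chance %.1f%%, %s%s)\n",
              mean(enc$accuracy), mean(enc$null_acc), tshow,
              if (enc$significance$significant) ", significant" else ""))
  for (cond in names(report$retrieval)) {
    mask <- report$retrieval[[cond]]$mask
    sig <- mask$time[mask$sig_joint]
    cat(sprintf("%s retrieval: %d percentile-significant, %d jointly significant bins%s\n",
                cond, sum(mask$sig_percentile), length(sig),
                if (length(sig)) paste0(" (", paste(range(sig), collapse = ".."),
                                        " s)") else ""))
  }
  if (!is.null(report$contrasts$de_success)) {
    sc <- report$contrasts$de_success
    cat(sprintf("DE success vs fail: t(%d) = %.2f, p = %.3g, d = %.2f (n = %d)\n",
                sc$df, sc$statistic, sc$p, sc$effect_size, sc$n))
  }
  if (!is.null(report$contrasts$ac_anova)) {
    cat("AC early/late x memory x context ANOVA:\n")
    print(report$contrasts$ac_anova, row.names = FALSE)
  }
  print(report$cluster)

  plots <- list(timecourse = plot_timecourses(report),
                confusion = plot_confusion(report))
  if (!is.null(report$searchlight))
    plots$searchlight <- plot_searchlight(report)
  invisible(plots)
}

#' Decoding timecourse plot with significant bins highlighted
#' @param report a `run_report`.
#' @return a ggplot object.
#' @export
plot_timecourses <- function(report) {
  df <- do.call(rbind, lapply(names(report$retrieval), function(cond) {
    r <- report$retrieval[[cond]]
    data.frame(condition = cond, time = r$observed$times,
               acc = colMeans(r$observed$acc),
               sig = r$mask$sig_joint)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = acc)) +
    ggplot2::geom_hline(yintercept = chance_level(), linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$sig, ], colour = "red", size = 1) +
    ggplot2::facet_wrap(~condition, ncol = 1) +
    ggplot2::labs(x = "time from cue onset (s)",
                  y = "target-context accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Mean confusion-matrix heatmap
#' @param report a `run_report`.
#' @return a ggplot object.
#' @export
plot_confusion <- function(report) {
  m <- report$encoding$mean_confusion
  df <- as.data.frame(as.table(m))
  names(df) <- c("true", "predicted", "proportion")
  ggplot2::ggplot(df, ggplot2::aes(predicted, true, fill = proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", proportion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::theme_minimal()
}

#' Searchlight accuracy maps
#' @param report a `run_report`.
#' @return a ggplot object (frequency map and channel map combined).
#' @export
plot_searchlight <- function(report) {
  sl <- report$searchlight
  fr <- data.frame(x = as.numeric(colnames(sl$freq_accuracy)),
                   accuracy = colMeans(sl$freq_accuracy),
                   significant = sl$freq_bonferroni$significant)
  ggplot2::ggplot(fr, ggplot2::aes(x, accuracy)) +
    ggplot2::geom_hline(yintercept = chance_level(), linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = significant)) +
    ggplot2::labs(x = "frequency (Hz)", y = "searchlight accuracy (%)") +
    ggplot2::theme_minimal()
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d subjects, seed %d, config %s\n",
              x$provenance$n_subjects, x$provenance$seed,
              x$provenance$config_hash))
  invisible(x)
}
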