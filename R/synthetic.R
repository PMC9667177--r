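#' Simulation configuration for a synthetic encode/retrieve EEG cohort
#'
#' Defaults encode the study design the pipeline targets: 62 recorded
#' channels (60 scalp + 2 mastoids) at 500 Hz; 18 blocks with four word-pairs
#' per condition per block; encoding epochs -1..7 s around movie onset;
#' retrieval epochs -2..6 s around cue onset with the probe at 2 s; three
#' contexts whose oscillatory signatures live in the 4-20 Hz band over the
#' most posterior 40% of scalp channels; per-condition recall rates ordered
#' AC < AB < DE (proactive interference); and a reinstatement schedule whose
#' windows match the headline replay effects (see
#' [default_reinstatement_schedule()]).
#'
#' @param n_subjects number of subjects.
#' @param n_channels total channels including the two mastoids.
#' @param fs sampling rate, Hz. `fs * 0.05` must be an integer so the 50-ms
#'   analysis grid falls on samples.
#' @param n_blocks experiment blocks.
#' @param pairs_per_condition_per_block word-pairs per condition per block.
#' @param encoding_trials_per_context encoding (movie) epochs per context per
#'   subject.
#' @param encoding_window,retrieval_window epoch limits in seconds.
#' @param cue_onset,probe_onset retrieval event times in seconds.
#' @param signature_band frequency interval (Hz) carrying context signatures.
#' @param posterior_channel_fraction fraction of scalp channels carrying
#'   signatures.
#' @param signature_cor_bound maximum pairwise correlation between the three
#'   context signature maps.
#' @param snr signature-to-noise amplitude ratio (0 = no signal).
#' @param noise_white_frac relative amplitude of the white sensor-noise
#'   component added to the 1/f background.
#' @param noise_alpha spectral exponent of the background (power ~ 1/f^alpha).
#' @param reinstatement_schedule list of [reinstatement_event()]s.
#' @param success_rates named per-condition recall probabilities.
#' @param drift_timescale seconds; when finite, signature amplitude follows a
#'   slow multiplicative random walk across trials (cosmetic; off by default).
#' @param seed integer seed; the cohort is a deterministic function of the
#'   full configuration.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_subjects,
                       n_channels = 62,
                       fs = 500,
                       n_blocks = 18,
                       pairs_per_condition_per_block = 4,
                       encoding_trials_per_context = 63,
                       encoding_window = c(-1, 7),
                       retrieval_window = c(-2, 6),
                       cue_onset = 0,
                       probe_onset = 2,
                       signature_band = c(4, 20),
                       posterior_channel_fraction = 0.4,
                       signature_cor_bound = 0.15,
                       snr = 1,
                       noise_white_frac = 0.3,
                       noise_alpha = 1,
                       reinstatement_schedule = default_reinstatement_schedule(),
                       success_rates = c(AB = 0.70, AC = 0.62, DE = 0.74),
                       drift_timescale = Inf,
                       seed = 1L) {
  stopifnot(n_subjects >= 1, n_channels >= 4, fs > 0,
            abs(fs * 0.05 - round(fs * 0.05)) < 1e-9,
            n_blocks >= 1, pairs_per_condition_per_block >= 2,
            pairs_per_condition_per_block %% 2 == 0,
            encoding_trials_per_context >= 1,
            snr >= 0, probe_onset > cue_onset,
            all(success_rates > 0 & success_rates < 1) ||
              all(success_rates > 0 & success_rates <= 1),
            signature_band[1] >= 4, signature_band[2] <= 45,
            signature_band[1] < signature_band[2],
            posterior_channel_fraction > 0, posterior_channel_fraction <= 1,
            all(c("AB", "AC", "DE") %in% names(success_rates)))
  cfg <- list(n_subjects = n_subjects, n_channels = n_channels, fs = fs,
              n_blocks = n_blocks,
              pairs_per_condition_per_block = pairs_per_condition_per_block,
              encoding_trials_per_context = encoding_trials_per_context,
              encoding_window = encoding_window,
              retrieval_window = retrieval_window,
              cue_onset = cue_onset, probe_onset = probe_onset,
              signature_band = signature_band,
              posterior_channel_fraction = posterior_channel_fraction,
              signature_cor_bound = signature_cor_bound,
              snr = snr, noise_white_frac = noise_white_frac,
              noise_alpha = noise_alpha,
              reinstatement_schedule = reinstatement_schedule,
              success_rates = success_rates,
              drift_timescale = drift_timescale,
              seed = as.integer(seed))
  for (ev in cfg$reinstatement_schedule) {
    if (ev$window[1] < retrieval_window[1] || ev$window[2] > retrieval_window[2])
      stop("reinstatement event window outside the retrieval epoch")
  }
  cfg$montage <- montage_subset(n_channels - 2L)
  class(cfg) <- "sim_config"
  cfg
}

#' A programmed reinstatement event
#'
#' Describes one burst of context-signature activity injected into retrieval
#' trials of a condition: whose context (target or competitor), when, how
#' strongly, and whether it appears only on successfully retrieved trials.
#'
#' @param condition `"AB"`, `"AC"` or `"DE"`.
#' @param which_context `"target"` or `"competitor"`.
#' @param window two seconds, relative to trial (cue) onset.
#' @param amplitude relative units (scales with the configured snr).
#' @param gated_by_success logical; inject only on successful trials.
#' @export
reinstatement_event <- function(condition, which_context, window,
                                amplitude = 1, gated_by_success = FALSE) {
  stopifnot(condition %in% c("AB", "AC", "DE"),
            which_context %in% c("target", "competitor"),
            length(window) == 2, window[1] < window[2], amplitude >= 0)
  if (condition == "DE" && which_context == "competitor")
    stop("DE trials have no competitor context")
  list(condition = condition, which_context = which_context,
       window = as.numeric(window), amplitude = amplitude,
       gated_by_success = isTRUE(gated_by_success))
}

#' Default reinstatement schedule
#'
#' The headline replay effects: target reinstatement at 0.9-1.0 s for
#' noncompetitive DE retrieval; for competitive AC retrieval, competitor
#' reinstatement at 2.35-2.45 s (present regardless of outcome) followed by
#' target reinstatement at 2.5-2.8 s; for AB retrieval, target reinstatement
#' at 2.5-2.8 s. Target effects are gated by retrieval success.
#' @return list of [reinstatement_event()]s.
#' @export
default_reinstatement_schedule <- function() {
  list(
    reinstatement_event("DE", "target", c(0.9, 1.0), 1, gated_by_success = TRUE),
    reinstatement_event("AC", "competitor", c(2.35, 2.45), 1, gated_by_success = FALSE),
    reinstatement_event("AC", "target", c(2.5, 2.8), 1, gated_by_success = TRUE),
    reinstatement_event("AB", "target", c(2.5, 2.8), 1, gated_by_success = TRUE)
  )
}

#' TFR frequency grid used throughout
#' @return integer Hz grid 4..45, step 1.
#' @export
default_freqs <- function() 4:45

#' Generate three distinguishable context signature maps
#'
#' Each map assigns a non-negative relative power increment to every
#' (scalp channel, frequency) cell; support is confined to the configured
#' posterior channel subset and signature band, weights are smoothed across
#' frequency, normalised to mean one over the support, and the three maps are
#' redrawn (rejection resampling) until every pairwise correlation over the
#' support falls below `signature_cor_bound`.
#'
#' @param config a [sim_config()].
#' @param freqs frequency grid the maps are defined on.
#' @param seed optional seed; when given, the maps are a deterministic
#'   function of it (inside [generate_cohort()] the cohort seed governs).
#' @return list of three `channels x frequencies` weight matrices (class
#'   `signature_map` each), with the scalp channel names as rownames.
#' @export
make_signatures <- function(config, freqs = default_freqs(), seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, make_signatures(config, freqs)))
  mont <- config$montage
  scalp <- mont$channel[mont$scalp]
  post <- posterior_channels(mont, config$posterior_channel_fraction)
  fband <- which(freqs >= config$signature_band[1] &
                 freqs <= config$signature_band[2])
  if (length(post) * length(fband) < 3)
    stop("channel subset too small to build three distinguishable signatures")
  draw_map <- function() {
    w <- matrix(0, length(scalp), length(freqs),
                dimnames = list(scalp, freqs))
    raw <- matrix(stats::rgamma(length(post) * length(fband), 2, 1),
                  length(post), length(fband))
    # smooth along frequency so maps look like band-limited spectra
    if (length(fband) >= 3)
      raw <- t(apply(raw, 1, function(r) moving_average(r, 3)))
    w[post, fband] <- raw / mean(raw)
    w
  }
  sup <- function(m) as.vector(m[post, fband, drop = FALSE])
  for (try in 1:200) {
    maps <- list(draw_map(), draw_map(), draw_map())
    cors <- c(cor(sup(maps[[1]]), sup(maps[[2]])),
              cor(sup(maps[[1]]), sup(maps[[3]])),
              cor(sup(maps[[2]]), sup(maps[[3]])))
    if (all(abs(cors) < config$signature_cor_bound)) {
      for (i in 1:3) class(maps[[i]]) <- c("signature_map", "matrix")
      names(maps) <- paste0("context", 1:3)
      return(maps)
    }
  }
  stop("could not draw three signature maps with pairwise correlation below ",
       config$signature_cor_bound)
}

# 1/f^alpha background plus white sensor noise for a block of traces,
# unit standard deviation per trace. n samples, m traces.
pink_noise <- function(n, m, fs, alpha, white_frac) {
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  amp <- f^(-alpha / 2)
  spec <- matrix(complex(real = rnorm(nf * m), imaginary = rnorm(nf * m)),
                 nf, m) * amp
  full <- matrix(0 + 0i, n, m)
  full[2:(nf + 1), ] <- spec
  full[seq(n, n - nf + 1), ] <- Conj(spec)
  x <- Re(mvfft(full, inverse = TRUE)) / n
  mu <- colMeans(x)
  x <- sweep(x, 2, mu)
  sdv <- sqrt(colSums(x^2) / (n - 1))
  x <- sweep(x, 2, sdv, "/")
  if (white_frac > 0) {
    x <- x + matrix(rnorm(n * m, sd = white_frac), n, m)
    x <- sweep(x, 2, sqrt(colSums(sweep(x, 2, colMeans(x))^2) / (n - 1)), "/")
  }
  x
}

# cosine-ramped on/off envelope over the epoch time axis
event_envelope <- function(times, window, ramp = 0.05) {
  ramp <- min(ramp, diff(window) / 4)
  env <- numeric(length(times))
  inside <- times >= window[1] & times <= window[2]
  env[inside] <- 1
  up <- times >= window[1] & times < window[1] + ramp
  env[up] <- 0.5 - 0.5 * cos(pi * (times[up] - window[1]) / ramp)
  dn <- times > window[2] - ramp & times <= window[2]
  env[dn] <- 0.5 - 0.5 * cos(pi * (window[2] - times[dn]) / ramp)
  env
}

#' Synthesise a single epoch
#'
#' One trial of `channels x samples` data: 1/f-shaped broadband noise plus,
#' for each reinstatement event, band-limited oscillatory bursts whose
#' channel-by-frequency envelope follows the event's signature map. Burst
#' amplitude is `snr * amplitude * weight` relative to the unit-variance
#' noise. Encoding trials are modelled by a single event spanning the movie
#' (0-6 s).
#'
#' @param signature default `signature_map` for events that do not carry
#'   their own.
#' @param events list of events; each needs `window`, `amplitude`, and
#'   optionally `signature`.
#' @param window epoch limits in seconds.
#' @param config a [sim_config()].
#' @param freqs frequency grid of the signature maps.
#' @return matrix `channels x samples` (scalp channels then mastoids), with
#'   channel names as rownames.
#' @export
synth_trial <- function(signature, events, window, config,
                        freqs = default_freqs()) {
  n <- round(diff(window) * config$fs)
  chans <- config$montage$channel
  x <- t(pink_noise(n, length(chans), config$fs, config$noise_alpha,
                    config$noise_white_frac))
  rownames(x) <- chans
  add_bursts(x, signature, events, window, config, freqs)
}

# oscillatory bursts for one trial, added onto a channels x samples matrix
add_bursts <- function(x, signature, events, window, config, freqs,
                       basis = NULL) {
  n <- ncol(x)
  times <- window[1] + (seq_len(n) - 1) / config$fs
  for (ev in events)
    if (ev$window[1] < window[1] - 1e-9 || ev$window[2] > window[2] + 1e-9)
      stop("event window [", ev$window[1], ", ", ev$window[2],
           "] outside the epoch window")
  if (config$snr == 0) return(x)
  for (ev in events) {
    sig <- ev$signature %||% signature
    nz <- which(sig > 0, arr.ind = TRUE)
    if (nrow(nz) == 0) next
    ch_names <- rownames(sig)[nz[, 1]]
    fr <- freqs[nz[, 2]]
    env <- event_envelope(times, ev$window)
    amp <- config$snr * ev$amplitude * sig[nz]
    ph <- runif(nrow(nz), 0, 2 * pi)
    # cos(2 pi f t + phi) = cos(phi) cos(2 pi f t) - sin(phi) sin(2 pi f t);
    # the cosine/sine bases can be shared across trials
    if (is.null(basis)) {
      wt <- outer(2 * pi * fr, times)
      C <- cos(wt); S <- sin(wt)
    } else {
      C <- basis$C; S <- basis$S
    }
    osc <- (amp * cos(ph)) * C - (amp * sin(ph)) * S
    bursts <- rowsum(osc * rep(env, each = nrow(osc)), ch_names)
    x[rownames(bursts), ] <- x[rownames(bursts), ] + bursts
  }
  x
}

# broadband background for a whole epoch set: trials x channels x samples
batch_noise <- function(n_trials, n, config) {
  x <- pink_noise(n, n_trials * config$n_channels, config$fs,
                  config$noise_alpha, config$noise_white_frac)
  aperm(array(x, c(n, config$n_channels, n_trials)), c(3, 2, 1))
}

#' Generate a synthetic multi-subject cohort
#'
#' Builds, per subject, encoding and retrieval [epochs()] with fully
#' specified ground truth. Contexts rotate over conditions across blocks
#' (counterbalanced assignment), encoding epochs carry their context's
#' signature throughout the movie window, retrieval epochs carry only the
#' scheduled reinstatement bursts, and recall success is drawn per condition
#' from `success_rates`. The analysed retrieval set mirrors the design:
#' per block, all noncompetitive pairs plus half of the AB and AC pairs, so
#' each cue appears once.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_cohort`: list with `subjects` (each holding
#'   `encoding`/`retrieval` epochs), `ground_truth` (signature maps and the
#'   realised schedule), and the generating `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- default_freqs()
  contexts <- c("underwater", "forest", "city")
  conditions <- c("AB", "AC", "DE")
  half <- config$pairs_per_condition_per_block / 2
  sched_cond <- vapply(config$reinstatement_schedule, `[[`, "", "condition")
  with_seed(config$seed, {
    subjects <- vector("list", config$n_subjects)
    truth <- vector("list", config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      sigs <- make_signatures(config, freqs)
      names(sigs) <- contexts
      # block-wise counterbalanced context -> condition rotation
      assign <- t(vapply(seq_len(config$n_blocks), function(b) {
        contexts[((b - 1 + 0:2) %% 3) + 1]
      }, character(3)))
      colnames(assign) <- conditions

      ## encoding: movie epochs, signature on for the whole 0-6 s movie span
      enc_ctx <- rep(contexts, each = config$encoding_trials_per_context)
      enc_block <- rep_len(seq_len(config$n_blocks), length(enc_ctx))
      n_enc_samp <- round(diff(config$encoding_window) * config$fs)
      enc_data <- batch_noise(length(enc_ctx), n_enc_samp, config)
      drift <- if (is.finite(config$drift_timescale))
        exp(cumsum(rnorm(length(enc_ctx), 0, 0.05))) else rep(1, length(enc_ctx))
      enc_times <- config$encoding_window[1] + (seq_len(n_enc_samp) - 1) / config$fs
      bases <- lapply(sigs, function(sg) {
        fr <- freqs[which(sg > 0, arr.ind = TRUE)[, 2]]
        wt <- outer(2 * pi * fr, enc_times)
        list(C = cos(wt), S = sin(wt))
      })
      for (i in seq_along(enc_ctx)) {
        ev <- list(list(window = c(0, 6), amplitude = drift[i]))
        x <- enc_data[i, , ]
        rownames(x) <- config$montage$channel
        enc_data[i, , ] <- add_bursts(x, sigs[[enc_ctx[i]]], ev,
                                      config$encoding_window, config, freqs,
                                      basis = bases[[enc_ctx[i]]])
      }
      enc_meta <- data.frame(subject = s, phase = "encoding",
                             block = enc_block, context = enc_ctx,
                             condition = NA_character_,
                             success = NA, stringsAsFactors = FALSE)

      ## retrieval: per block 4 DE + half of AB and AC pairs (first-eight set)
      ret_rows <- do.call(rbind, lapply(seq_len(config$n_blocks), function(b) {
        n_by_cond <- c(AB = half, AC = half,
                       DE = config$pairs_per_condition_per_block)
        data.frame(block = b,
                   condition = rep(names(n_by_cond), n_by_cond),
                   stringsAsFactors = FALSE)
      }))
      ret_rows$target_context <- assign[cbind(ret_rows$block,
                                              match(ret_rows$condition, conditions))]
      comp_cond <- c(AB = "AC", AC = "AB", DE = NA)[ret_rows$condition]
      ret_rows$competitor_context <- ifelse(
        is.na(comp_cond), NA_character_,
        assign[cbind(ret_rows$block,
                     match(comp_cond, conditions))])
      ret_rows$success <- rbinom(nrow(ret_rows), 1,
                                 config$success_rates[ret_rows$condition]) == 1
      n_ret_samp <- round(diff(config$retrieval_window) * config$fs)
      ret_data <- batch_noise(nrow(ret_rows), n_ret_samp, config)
      ret_times_ax <- config$retrieval_window[1] + (seq_len(n_ret_samp) - 1) / config$fs
      ret_bases <- lapply(sigs, function(sg) {
        fr <- freqs[which(sg > 0, arr.ind = TRUE)[, 2]]
        wt <- outer(2 * pi * fr, ret_times_ax)
        list(C = cos(wt), S = sin(wt))
      })
      for (i in seq_len(nrow(ret_rows))) {
        for (k in which(sched_cond == ret_rows$condition[i])) {
          ev <- config$reinstatement_schedule[[k]]
          if (ev$gated_by_success && !ret_rows$success[i]) next
          ctx <- if (ev$which_context == "target") ret_rows$target_context[i]
                 else ret_rows$competitor_context[i]
          if (is.na(ctx)) next
          x <- ret_data[i, , ]
          rownames(x) <- config$montage$channel
          ret_data[i, , ] <- add_bursts(
            x, sigs[[ctx]],
            list(list(window = ev$window, amplitude = ev$amplitude)),
            config$retrieval_window, config, freqs,
            basis = ret_bases[[ctx]])
        }
      }
      ret_meta <- data.frame(subject = s, phase = "retrieval",
                             block = ret_rows$block, context = ret_rows$target_context,
                             condition = ret_rows$condition,
                             target_context = ret_rows$target_context,
                             competitor_context = ret_rows$competitor_context,
                             success = ret_rows$success, stringsAsFactors = FALSE)

      subjects[[s]] <- list(
        encoding = epochs(enc_data, config$fs, config$encoding_window[1],
                          config$montage$channel, enc_meta),
        retrieval = epochs(ret_data, config$fs, config$retrieval_window[1],
                           config$montage$channel, ret_meta))
      truth[[s]] <- list(signatures = sigs, block_assignment = assign)
    }
  })
  usable <- vapply(subjects, function(su) {
    any(su$retrieval$metadata$success) && any(!su$retrieval$metadata$success)
  }, logical(1))
  structure(list(subjects = subjects,
                 ground_truth = list(per_subject = truth,
                                     schedule = config$reinstatement_schedule),
                 success_failure_contrast_usable = all(usable),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d channels @ %g Hz, snr = %g\n",
              length(x$subjects), x$config$n_channels, x$config$fs,
              x$config$snr))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Per subject and phase one epoch container ([write_epochs()]) plus a single
#' tab-delimited behavioural table (subject, block, condition, success).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beh <- NULL
  for (s in seq_along(cohort$subjects)) {
    su <- cohort$subjects[[s]]
    write_epochs(su$encoding, file.path(dir, sprintf("sub%02d_encoding", s)))
    write_epochs(su$retrieval, file.path(dir, sprintf("sub%02d_retrieval", s)))
    md <- su$retrieval$metadata
    beh <- rbind(beh, md[, c("subject", "block", "condition", "success")])
  }
  utils::write.table(beh, file.path(dir, "behavior.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
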