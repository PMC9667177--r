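# Shared fixtures: reduced-size configurations and cached cohorts/preps so
# expensive objects are built once per test run.

# reduced frequency grids used by the desk-scale tests
freqs_desk <- seq(4, 44, 2)   # 21 frequencies, same 4-45 Hz span
freqs_tiny <- seq(4, 24, 2)   # 11 frequencies, for the smallest cohorts

# small cohort configuration factory
desk_cfg <- function(n_subjects = 8, n_channels = 10, fs = 100, n_blocks = 3,
                     enc = 12, snr = 0, seed = 1, ...) {
  sim_config(n_subjects = n_subjects, n_channels = n_channels, fs = fs,
             n_blocks = n_blocks, encoding_trials_per_context = enc,
             snr = snr, seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

# memoised cohort + per-subject preparations
fixture_preps <- function(name, cfg, freqs = freqs_desk) {
  if (is.null(.fixture_env[[name]])) {
    cohort <- generate_cohort(cfg)
    .fixture_env[[name]] <- list(
      cohort = cohort,
      preps = lapply(cohort$subjects, prepare_decoding, freqs = freqs))
  }
  .fixture_env[[name]]
}

# a small signal-bearing cohort shared by decoder/stats tests
signal_fixture <- function() {
  fixture_preps("signal",
                desk_cfg(n_subjects = 4, n_blocks = 2, enc = 10, snr = 2,
                         seed = 42))
}

# random epochs with named channels, for preprocessing tests
random_epochs <- function(n_trials = 4, n_channels = 4, n_samples = 200,
                          fs = 100, t0 = -0.5, seed = 1,
                          channels = c("C1", "C2", "M1", "M2")) {
  set.seed(seed)
  epochs(array(rnorm(n_trials * n_channels * n_samples),
               c(n_trials, n_channels, n_samples)),
         fs, t0, channels[seq_len(n_channels)],
         data.frame(trial = seq_len(n_trials),
                    condition = rep(c("DE", "AC"), length.out = n_trials)))
}

# brute-force flood fill over an explicit adjacency list (independent oracle
# for the graph-component clustering)
flood_fill_components <- function(cells, adj) {
  remaining <- cells
  comps <- list()
  while (length(remaining)) {
    queue <- remaining[1]
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!(v %in% remaining)) next
      remaining <- setdiff(remaining, v)
      comp <- c(comp, v)
      queue <- c(queue, intersect(adj[[v]], remaining))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}
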