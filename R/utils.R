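#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the master seed and the stage name, so a single integer reproduces a
#' whole run while stages stay independent of each other's consumption of
#' random numbers.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) %% 94906265) * 22.0 + (h %% 1000003)) %% 2147483647L
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Centred moving average with shrinking edges
#'
#' Averages over a centred window of `k` points; near the series edges the
#' window shrinks to the available points, so the output has the same length
#' and no padding bias.
#'
#' @param x numeric vector.
#' @param k odd window length in points.
#' @return numeric vector, `length(x)`.
#' @export
moving_average <- function(x, k) {
  stopifnot(k >= 1, k %% 2 == 1)
  n <- length(x)
  if (k == 1 || n == 1) return(x)
  h <- (k - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# odd number of bins covered by a time window on a bin grid
smoothing_bins <- function(window, step) {
  k <- ceiling(window / step - 1e-9)
  if (k %% 2 == 0) k <- k + 1
  as.integer(max(k, 1))
}

#' Chance level for three-way classification, in percent
#' @export
chance_level <- function() 100 / 3

`%||%` <- function(a, b) if (is.null(a)) b else a
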