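#' Approximate extended 10-20 montage (60 scalp channels + linked mastoids)
#'
#' A 2-D projected layout of the 62-channel recording set used throughout the
#' package: 60 scalp electrodes named after the extended 10-20 system plus
#' the two mastoids `M1`/`M2`. Coordinates are an approximate synthetic
#' projection built from row/column geometry (anterior-posterior rows,
#' left-right columns); they are used for neighbourhood graphs and for
#' selecting posterior channels, not for source modelling.
#'
#' @return data.frame with columns `channel`, `x`, `y`, `scalp` (logical).
#' @export
montage62 <- function() {
  rows <- list(
    FP = list(y = 0.92, w = 0.35, ch = c("FP1", "FPZ", "FP2")),
    AF = list(y = 0.76, w = 0.30, ch = c("AF3", "AF4")),
    F  = list(y = 0.55, w = 0.75, ch = c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8")),
    FC = list(y = 0.28, w = 0.90, ch = c("FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8")),
    C  = list(y = 0.00, w = 1.00, ch = c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8")),
    CP = list(y = -0.28, w = 0.90, ch = c("TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8")),
    P  = list(y = -0.55, w = 0.75, ch = c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8")),
    PO = list(y = -0.76, w = 0.50, ch = c("PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8")),
    O  = list(y = -0.92, w = 0.30, ch = c("O1", "OZ", "O2"))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    n <- length(r$ch)
    x <- if (n == 1) 0 else seq(-1, 1, length.out = n) * r$w
    data.frame(channel = r$ch, x = x, y = r$y, scalp = TRUE,
               stringsAsFactors = FALSE)
  }))
  out <- rbind(out,
               data.frame(channel = c("M1", "M2"), x = c(-1.15, 1.15),
                          y = -0.15, scalp = FALSE))
  rownames(out) <- NULL
  out
}

#' Evenly thinned montage subset
#'
#' Deterministically selects `n_scalp` scalp channels spread along the
#' anterior-posterior axis (mastoids are always kept), for reduced-size
#' simulations where the full 60-channel set is not needed.
#'
#' @param n_scalp number of scalp channels to keep (2..60).
#' @return montage data.frame as [montage62()].
#' @export
montage_subset <- function(n_scalp = 60) {
  m <- montage62()
  scalp <- m[m$scalp, ]
  stopifnot(n_scalp >= 2, n_scalp <= nrow(scalp))
  ord <- order(scalp$y, scalp$x)
  keep <- ord[round(seq(1, nrow(scalp), length.out = n_scalp))]
  out <- rbind(scalp[sort(keep), ], m[!m$scalp, ])
  rownames(out) <- NULL
  out
}

#' Nearest-neighbour channel adjacency graph
#'
#' Each scalp channel is linked to its `k` nearest scalp channels in the
#' projected layout and the relation is symmetrised (a union of the two
#' directions), which on the full montage yields neighbourhoods of roughly
#' four to eight channels, matching typical template neighbour counts for
#' this electrode density.
#'
#' @param montage montage data.frame ([montage62()]).
#' @param k number of nearest neighbours before symmetrisation.
#' @return named list mapping each scalp channel to its neighbour names.
#' @export
channel_neighbors <- function(montage = montage62(), k = 5) {
  s <- montage[montage$scalp, ]
  k <- min(k, nrow(s) - 1L)
  d <- as.matrix(stats::dist(s[, c("x", "y")]))
  diag(d) <- Inf
  near <- lapply(seq_len(nrow(s)), function(i) order(d[i, ])[seq_len(k)])
  nb <- lapply(seq_len(nrow(s)), function(i) {
    mutual <- union(near[[i]],
                    which(vapply(near, function(v) i %in% v, TRUE)))
    sort(s$channel[mutual])
  })
  names(nb) <- s$channel
  nb
}

#' Posterior channel subset
#'
#' The `fraction` most posterior scalp channels (lowest projected y), the
#' region where context signatures concentrate.
#'
#' @param montage montage data.frame.
#' @param fraction proportion of scalp channels to select.
#' @return character vector of channel names.
#' @export
posterior_channels <- function(montage = montage62(), fraction = 0.4) {
  s <- montage[montage$scalp, ]
  k <- max(1L, round(fraction * nrow(s)))
  s$channel[order(s$y, s$x)][seq_len(k)]
}
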