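#' Epoched multichannel EEG
#'
#' Container for epoched EEG: a `trials x channels x samples` array, the
#' sampling rate, the time of the first sample relative to the trial event,
#' channel names, and a per-trial metadata table (subject, phase, context,
#' condition, success, ...). All trials share the time axis.
#'
#' @param data numeric array `trials x channels x samples`.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds relative to the event.
#' @param channel_names character vector, one per channel.
#' @param metadata data.frame with one row per trial.
#' @return an object of class `eeg_epochs`.
#' @export
epochs <- function(data, fs, t0, channel_names, metadata) {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0)
  stopifnot(length(channel_names) == dim(data)[2])
  stopifnot(is.data.frame(metadata), nrow(metadata) == dim(data)[1])
  structure(list(data = data, fs = fs, t0 = t0,
                 channel_names = as.character(channel_names),
                 metadata = metadata),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              d[1], d[2], d[3], x$fs, x$t0))
  invisible(x)
}

#' Time axis of an epochs object
#' @param x an `eeg_epochs` object.
#' @return numeric vector of sample times in seconds.
#' @export
epoch_times <- function(x) x$t0 + (seq_len(dim(x$data)[3]) - 1) / x$fs

#' Number of trials
#' @param x an `eeg_epochs` object.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' Re-reference to linked mastoids
#'
#' Subtracts the mean of the two mastoid channels from every sample and drops
#' the mastoids from the channel set.
#'
#' @param x an `eeg_epochs` object.
#' @param left,right mastoid channel names.
#' @return re-referenced `eeg_epochs` without the mastoid channels.
#' @export
rereference_linked_mastoids <- function(x, left = "M1", right = "M2") {
  idx <- match(c(left, right), x$channel_names)
  if (anyNA(idx))
    stop("mastoid channel(s) not present: ",
         paste(c(left, right)[is.na(idx)], collapse = ", "))
  ref <- (x$data[, idx[1], , drop = FALSE] + x$data[, idx[2], , drop = FALSE]) / 2
  keep <- setdiff(seq_along(x$channel_names), idx)
  out <- x$data[, keep, , drop = FALSE]
  out <- out - ref[, rep(1, length(keep)), , drop = FALSE]
  epochs(out, x$fs, x$t0, x$channel_names[keep], x$metadata)
}

#' Whole-epoch mean baseline correction
#'
#' Removes, per trial and channel, the temporal mean over the whole epoch.
#'
#' @param x an `eeg_epochs` object.
#' @return baseline-corrected `eeg_epochs`.
#' @export
baseline_epoch_mean <- function(x) {
  mu <- rowMeans(x$data, dims = 2)
  x$data <- x$data - as.vector(mu)  # recycles over the samples dimension
  x
}

#' Downsample with anti-alias filtering
#'
#' Zero-phase FIR low-pass (cutoff `0.4 * target_fs`, Hamming window, order
#' `32 * factor`) followed by decimation. The target rate must divide the
#' current rate.
#'
#' @param x an `eeg_epochs` object.
#' @param target_fs target sampling rate in Hz.
#' @return downsampled `eeg_epochs`.
#' @export
downsample_epochs <- function(x, target_fs) {
  r <- x$fs / target_fs
  if (abs(r - round(r)) > 1e-9)
    stop("target_fs must divide fs (", x$fs, " -> ", target_fs, ")")
  r <- round(r)
  if (r == 1L) return(x)
  w <- 0.8 * target_fs / x$fs  # cutoff 0.4 * target_fs, normalised to Nyquist
  b <- as.numeric(signal::fir1(32L * r, w))
  d <- dim(x$data)
  nout <- floor(d[3] / r)
  out <- array(0, c(d[1], d[2], nout))
  keep <- seq(1L, by = r, length.out = nout)
  for (tr in seq_len(d[1])) for (ch in seq_len(d[2])) {
    f <- signal::filtfilt(b, 1, x$data[tr, ch, ])
    out[tr, ch, ] <- f[keep]
  }
  epochs(out, target_fs, x$t0, x$channel_names, x$metadata)
}

#' Filter trials by metadata
#'
#' Keeps the trials whose metadata row satisfies `predicate`; trial order and
#' metadata alignment are preserved. An empty selection is a warning, not an
#' error.
#'
#' @param x an `eeg_epochs` object.
#' @param predicate function taking the metadata data.frame and returning a
#'   logical vector over trials.
#' @return filtered `eeg_epochs`.
#' @export
select_trials <- function(x, predicate) {
  keep <- predicate(x$metadata)
  stopifnot(is.logical(keep), length(keep) == n_trials(x))
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("select_trials: empty selection")
  epochs(x$data[keep, , , drop = FALSE], x$fs, x$t0, x$channel_names,
         x$metadata[keep, , drop = FALSE])
}

#' Apply an externally supplied artifact keep-mask
#'
#' Manual artifact screening is not reproducible from a text description, so
#' the package accepts a per-trial logical mask produced elsewhere and simply
#' filters by it.
#'
#' @param x an `eeg_epochs` object.
#' @param keep logical vector over trials.
#' @return filtered `eeg_epochs`.
#' @export
apply_keep_mask <- function(x, keep) {
  stopifnot(is.logical(keep), length(keep) == n_trials(x))
  select_trials(x, function(md) keep)
}

#' Write epochs as a portable array container
#'
#' One little-endian 32-bit float binary file (`<name>.f32`, trial-major:
#' sample fastest, then channel, then trial) plus a JSON sidecar
#' (`<name>.json`) holding `fs`, `t0`, `dim`, `channel_names` and the
#' per-trial metadata table.
#'
#' @param x an `eeg_epochs` object.
#' @param path file path without extension.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  con <- file(paste0(path, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(x$data, c(3, 2, 1))), con, size = 4,
           endian = "little")
  side <- list(fs = x$fs, t0 = x$t0, dim = dim(x$data),
               channel_names = x$channel_names, metadata = x$metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an epochs container written by [write_epochs()]
#' @param path file path without extension.
#' @return an `eeg_epochs` object.
#' @export
read_epochs <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(side$dim)
  con <- file(paste0(path, ".f32"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = prod(d), size = 4, endian = "little")
  data <- aperm(array(raw, d[c(3, 2, 1)]), c(3, 2, 1))
  epochs(data, side$fs, side$t0, side$channel_names,
         as.data.frame(side$metadata))
}

#' Export per-trial metadata as tab-delimited text
#' @param x an `eeg_epochs` object.
#' @param file output path.
#' @export
export_metadata <- function(x, file) {
  utils::write.table(x$metadata, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
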