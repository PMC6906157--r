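#' Epoched EEG container
#'
#' Holds epoched multichannel EEG as a trials x channels x samples array in
#' microvolts, together with timing metadata, channel labels, the reference
#' state and a per-trial artifact mask. Trial-level behavior (true category,
#' decision, RT, ...) travels alongside in the `trials` tibble.
#'
#' @param data Numeric array, trials x channels x samples (microvolts).
#' @param sfreq Sampling frequency in Hz.
#' @param times Numeric vector of sample times in ms relative to stimulus
#'   onset; length must equal `dim(data)[3]`.
#' @param channels Character vector of channel labels (10/5 system).
#' @param trials Optional tibble with one row per trial.
#' @param reference `"raw"` or `"average"`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sfreq, times, channels, trials = NULL,
                      reference = "raw") {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(times) != dim(data)[3]) {
    stop("`times` length must match the sample dimension", call. = FALSE)
  }
  if (length(channels) != dim(data)[2]) {
    stop("`channels` length must match the channel dimension", call. = FALSE)
  }
  if (!is.null(trials) && nrow(trials) != dim(data)[1]) {
    stop("`trials` must have one row per epoch", call. = FALSE)
  }
  structure(
    list(
      data = data, sfreq = sfreq, times = as.numeric(times),
      channels = as.character(channels),
      reference = match.arg(reference, c("raw", "average")),
      artifact_mask = logical(dim(data)[1]),
      trials = trials
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz, %s reference\n",
    d[1], d[2], d[3], x$sfreq, x$reference))
  cat(sprintf("  window %g..%g ms; %d trial(s) flagged as artifact\n",
              min(x$times), max(x$times), sum(x$artifact_mask)))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials <- function(epochs) dim(epochs$data)[1]

# Subset trials, keeping metadata aligned.
subset_trials <- function(epochs, keep) {
  keep <- if (is.logical(keep)) which(keep) else keep
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$artifact_mask <- epochs$artifact_mask[keep]
  if (!is.null(epochs$trials)) epochs$trials <- epochs$trials[keep, ]
  epochs
}

# Default epoch time axis: -200..1000 ms at 256 Hz (307 samples).
default_times <- function(sfreq = 256, window = c(-200, 1000)) {
  n <- round(diff(window) / 1000 * sfreq)
  seq(window[1], by = 1000 / sfreq, length.out = n)
}

#' Write / read an epoch container directory
#'
#' The on-disk container is a directory with `epochs.f32` (row-major float32,
#' trials x channels x samples), `meta.json` (sampling rate, times, channels,
#' reference) and `trials.csv`.
#'
#' @param epochs An [epoch_set()].
#' @param path Directory to create/read.
#' @return `write_epoch_set` returns `path` invisibly; `read_epoch_set`
#'   returns an [epoch_set()].
#' @export
write_epoch_set <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs$data)
  con <- file(file.path(path, "epochs.f32"), "wb")
  on.exit(close(con))
  # row-major: trial, then channel, then sample
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con, size = 4L)
  meta <- list(
    dim = d, sfreq = epochs$sfreq, times = epochs$times,
    channels = epochs$channels, reference = epochs$reference,
    artifact_mask = epochs$artifact_mask
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(epochs$trials)) {
    utils::write.csv(epochs$trials, file.path(path, "trials.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  con <- file(file.path(path, "epochs.f32"), "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "numeric", n = prod(d), size = 4L)
  data <- aperm(array(raw, dim = rev(d)), c(3, 2, 1))
  trials_file <- file.path(path, "trials.csv")
  trials <- if (file.exists(trials_file)) {
    tibble::as_tibble(utils::read.csv(trials_file))
  }
  out <- epoch_set(data, meta$sfreq, meta$times, meta$channels,
                   trials = trials, reference = meta$reference)
  out$artifact_mask <- as.logical(meta$artifact_mask)
  out
}
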