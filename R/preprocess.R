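#' Zero-phase band-pass filter for epoched EEG
#'
#' Applies a zero-phase band-pass (default 0.1--30 Hz) to every
#' trial/channel time series. The filter is realized in the frequency
#' domain: each series is reflection-padded to three epoch lengths, its
#' spectrum multiplied by a real raised-cosine amplitude response (so the
#' phase response is identically zero), and transformed back. The DC bin is
#' always zeroed; the high edge uses a 4 Hz raised-cosine transition. On
#' 1.2 s epochs the 0.1 Hz high-pass edge necessarily acts as DC/drift
#' removal -- a time-domain FIR with a sub-0.1 Hz transition would need far
#' more taps than the epoch has samples.
#'
#' @param epochs An [epoch_set()].
#' @param low,high Band edges in Hz, `0 < low < high < sfreq/2`.
#' @return The filtered [epoch_set()].
#' @export
bandpass_filter <- function(epochs, low = 0.1, high = 30) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!(low > 0 && low < high && high < epochs$sfreq / 2)) {
    stop("band edges must satisfy 0 < low < high < sfreq/2", call. = FALSE)
  }
  d <- dim(epochs$data)
  n_s <- d[3]
  n_pad <- 3L * n_s
  f <- (seq_len(n_pad) - 1L) / n_pad * epochs$sfreq
  f <- pmin(f, epochs$sfreq - f) # two-sided frequency axis
  resp <- bandpass_response(f, low, high)
  mid <- (n_s + 1L):(2L * n_s)
  for (t in seq_len(d[1])) {
    x <- t(epochs$data[t, , , drop = TRUE])
    if (d[2] == 1L) x <- matrix(x, ncol = 1L)
    xp <- rbind(x[n_s:1, , drop = FALSE], x, x[n_s:1, , drop = FALSE])
    xf <- stats::mvfft(xp)
    y <- Re(stats::mvfft(xf * resp, inverse = TRUE)) / n_pad
    epochs$data[t, , ] <- t(y[mid, , drop = FALSE])
  }
  epochs
}

#' Amplitude response of the band-pass filter
#'
#' Evaluates the zero-phase raised-cosine amplitude response used by
#' [bandpass_filter()] at the given frequencies; useful for verifying
#' attenuation (e.g. at 0, 50 or 60 Hz).
#'
#' @param f Frequencies in Hz.
#' @param low,high Band edges in Hz.
#' @return Amplitude response in `[0, 1]`.
#' @export
bandpass_response <- function(f, low = 0.1, high = 30) {
  hp_lo <- low / 2
  hp_hi <- low * 1.5
  hp <- ifelse(f <= hp_lo, 0,
               ifelse(f >= hp_hi, 1,
                      0.5 * (1 - cos(pi * (f - hp_lo) / (hp_hi - hp_lo)))))
  lp_hi <- high + 4
  lp <- ifelse(f <= high, 1,
               ifelse(f >= lp_hi, 0,
                      0.5 * (1 + cos(pi * (f - high) / 4))))
  out <- hp * lp
  out[f == 0] <- 0
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus baseline
#' window (default -200..0 ms).
#'
#' @param epochs An [epoch_set()].
#' @param window Length-2 ms window; must lie inside the epoch times.
#' @return The corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$times >= window[1] & epochs$times <= window[2])
  if (length(idx) == 0) stop("empty baseline window", call. = FALSE)
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base) # recycles over samples
  epochs
}

#' Average-reference epochs
#'
#' Removes the across-channel mean at every (trial, sample); sets the
#' reference flag and reduces the data rank by one.
#'
#' @param epochs An [epoch_set()] with at least 2 channels.
#' @return The re-referenced [epoch_set()].
#' @export
average_reference <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[2] < 2) stop("need >= 2 channels", call. = FALSE)
  d <- dim(epochs$data)
  chan_mean <- apply(epochs$data, c(1, 3), mean) # trials x samples
  epochs$data <- epochs$data -
    aperm(array(chan_mean, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs$reference <- "average"
  epochs
}

#' Flag artifact trials by peak-to-peak amplitude
#'
#' Marks every trial whose peak-to-peak amplitude on any channel exceeds the
#' threshold; flagged trials are excluded from downstream fitting. The
#' criterion (default 150 microvolts) is a configuration key.
#'
#' @param epochs An [epoch_set()].
#' @param threshold Peak-to-peak threshold in microvolts (> 0).
#' @return The [epoch_set()] with `artifact_mask` updated.
#' @export
reject_artifacts <- function(epochs, threshold = 150) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  ptp <- apply(epochs$data, c(1, 2), function(x) max(x) - min(x))
  flagged <- apply(ptp, 1, max) > threshold
  if (all(flagged)) {
    stop("all trials exceed the artifact threshold; revise the threshold",
         call. = FALSE)
  }
  epochs$artifact_mask <- flagged
  if (!is.null(epochs$trials)) epochs$trials$artifact_flagged <- flagged
  epochs
}

#' Interpolate bad channels
#'
#' Replaces each listed channel by an inverse-distance-weighted average of
#' its `k` nearest good neighbors on the idealized spherical 10/5 layout
#' (a simplification of spherical-spline interpolation).
#'
#' @param epochs An [epoch_set()].
#' @param bad_channels Character vector of channel labels (strict subset).
#' @param k Number of neighbors.
#' @return The [epoch_set()] with listed channels replaced.
#' @export
interpolate_channels <- function(epochs, bad_channels, k = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(bad_channels) == 0) return(epochs)
  bad <- match(bad_channels, epochs$channels)
  if (anyNA(bad)) stop("unknown channel label(s)", call. = FALSE)
  good <- setdiff(seq_along(epochs$channels), bad)
  if (length(good) == 0) stop("all channels marked bad", call. = FALSE)
  pos <- montage_positions(epochs$channels)
  for (b in bad) {
    d <- sqrt(rowSums((pos[good, , drop = FALSE] -
                         matrix(pos[b, ], length(good), 3,
                                byrow = TRUE))^2))
    nb <- good[order(d)][seq_len(min(k, length(good)))]
    w <- 1 / pmax(sort(d)[seq_along(nb)], 1e-9)
    w <- w / sum(w)
    acc <- 0
    for (j in seq_along(nb)) {
      acc <- acc + w[j] * epochs$data[, nb[j], , drop = FALSE]
    }
    epochs$data[, b, ] <- acc[, 1, ]
  }
  epochs
}

#' Run the standard preprocessing chain
#'
#' Applies, in order: artifact scoring, bad-channel interpolation, average
#' referencing, band-pass filtering and baseline correction (epoching has
#' already happened at container construction). The order is enforced here
#' so individual steps cannot be rearranged by accident.
#'
#' @param epochs An [epoch_set()].
#' @param artifact_threshold Peak-to-peak criterion, microvolts.
#' @param bad_channels Channels to interpolate (default none).
#' @param low,high Band edges, Hz.
#' @param baseline_window Baseline window, ms.
#' @param drop_artifacts If `TRUE` (default) flagged trials are removed from
#'   the returned container.
#' @return The preprocessed [epoch_set()].
#' @export
preprocess <- function(epochs, artifact_threshold = 150,
                       bad_channels = character(), low = 0.1, high = 30,
                       baseline_window = c(-200, 0),
                       drop_artifacts = TRUE) {
  epochs <- reject_artifacts(epochs, artifact_threshold)
  epochs <- interpolate_channels(epochs, bad_channels)
  epochs <- average_reference(epochs)
  epochs <- bandpass_filter(epochs, low, high)
  epochs <- baseline_correct(epochs, baseline_window)
  if (drop_artifacts) epochs <- subset_trials(epochs, !epochs$artifact_mask)
  epochs
}
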