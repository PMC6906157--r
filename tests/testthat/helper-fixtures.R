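# Programmatic fixtures shared across test files.

# Random epochs with a standard -200..1000 ms axis.
make_test_epochs <- function(n_trials = 8, n_channels = 8, sfreq = 256,
                             seed = 42, fill = NULL) {
  times <- seq(-200, by = 1000 / sfreq, length.out = round(1.2 * sfreq))
  withr::with_seed(seed, {
    data <- array(stats::rnorm(n_trials * n_channels * length(times)),
                  dim = c(n_trials, n_channels, length(times)))
    if (!is.null(fill)) data[] <- fill
    chans <- standard_montage(max(n_channels, 4))$channel[seq_len(n_channels)]
    epoch_set(data, sfreq, times, chans)
  })
}

# Deterministic two-channel CSP toy: per-trial covariance exactly
# diag(4.5, 0.5) (class 1) or diag(0.5, 4.5) (class 2) via full-period
# sinusoids, so the trace-normalized class covariances are diag(0.9, 0.1)
# and diag(0.1, 0.9) exactly.
make_csp_toy <- function(n_per_class = 4, n_samples = 64) {
  tt <- seq(0, n_samples - 1) / n_samples
  s <- sin(2 * pi * 4 * tt)
  c_ <- cos(2 * pi * 4 * tt)
  data <- array(0, dim = c(2 * n_per_class, 2, n_samples))
  for (t in seq_len(n_per_class)) {
    data[t, 1, ] <- 3 * s
    data[t, 2, ] <- 1 * c_
    data[n_per_class + t, 1, ] <- 1 * s
    data[n_per_class + t, 2, ] <- 3 * c_
  }
  times <- seq(0, by = 1000 / 256, length.out = n_samples)
  list(
    epochs = epoch_set(data, 256, times, c("C3", "C4")),
    classes = rep(1:2, each = n_per_class)
  )
}

# A fully analyzed small synthetic participant, computed once per test run
# and reused (features, trials, and ground truth).
participant_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_trials = 240, p = 0.7, lapse = 0, snr = 2,
                           nonresponse_rate = 0, artifact_rate = 0,
                           master_seed = 77)
      sim <- simulate_participant(cfg, 1)
      clean <- preprocess(sim$epochs)
      wh <- reduce_whiten(clean)
      comp <- apply_transform(clean, wh)
      csp <- fit_csp(comp, clean$trials$decision)
      feats <- extract_features(comp, csp)
      cache <<- list(sim = sim, clean = clean, csp = csp,
                     features = feats, trials = clean$trials)
    }
    cache
  }
})
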