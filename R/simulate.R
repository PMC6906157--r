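#' Synthetic cohort configuration
#'
#' Collects the generative settings for a synthetic EEG/behavior cohort:
#' per-trial perceptual accuracy (probability that the latent perception
#' matches the true category), decision lapse rate, EEG signal-to-noise
#' ratio, channel count, recording parameters, attrition rates and the
#' workload coupling. Everything downstream is deterministic given
#' `master_seed`.
#'
#' Defaults mirror the study's task and recording parameters: 256 Hz
#' sampling, -200..1000 ms epochs, two tasks emulated by two perceptual
#' accuracy settings (II 0.72, RB 0.65, chosen near the reported group mean
#' accuracies so the II > RB ordering is reproduced), 240 trials per task,
#' and low non-response (1%) and artifact (5%) rates to exercise attrition
#' handling.
#'
#' @param n_participants Number of participants.
#' @param n_trials Trials per participant and task.
#' @param p Perceptual accuracy in (0,1); either a scalar or a length-2
#'   range from which each participant's accuracy is drawn uniformly.
#' @param lapse Probability that the decision flips relative to the latent
#'   perception.
#' @param snr Nonnegative perception-signal to background-noise amplitude
#'   ratio: at the evoked-waveform peak, the Euclidean norm of the signal
#'   topography across the array equals `2 snr` times the per-channel
#'   background RMS. The scale is calibrated so that `snr = 0` is pure
#'   noise, `snr = 2` is reliably decodable single-trial signal, and
#'   individual channels stay at physiological ERP amplitudes.
#' @param n_channels Number of EEG channels (4--72).
#' @param sfreq Sampling frequency, Hz.
#' @param epoch_window Epoch window in ms relative to stimulus onset.
#' @param noise_sd Background per-channel RMS amplitude, microvolts.
#' @param nonresponse_rate,artifact_rate Simulated attrition rates.
#' @param workload_coupling Named vector `c(intercept, slope, sd)` coupling
#'   the workload score to the participant's true resource parameter.
#' @param task Task variant used for stimulus sampling (`"II"` or `"RB"`).
#' @param master_seed Integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 48, n_trials = 240, p = 0.72,
                          lapse = 0.02, snr = 2, n_channels = 32,
                          sfreq = 256, epoch_window = c(-200, 1000),
                          noise_sd = 10,
                          nonresponse_rate = 0.01, artifact_rate = 0.05,
                          workload_coupling = c(intercept = 0.55,
                                                slope = 0.1, sd = 0.03),
                          task = "II", master_seed = 1L) {
  if (length(p) == 1L) assert_prob(p, "p") else {
    stopifnot(length(p) == 2L, all(p > 0 & p < 1), p[1] < p[2])
  }
  assert_prob(lapse, "lapse", open_low = FALSE)
  if (snr < 0) stop("`snr` must be nonnegative", call. = FALSE)
  assert_prob(nonresponse_rate, "nonresponse_rate", open_low = FALSE)
  assert_prob(artifact_rate, "artifact_rate", open_low = FALSE)
  structure(
    list(n_participants = n_participants, n_trials = n_trials, p = p,
         lapse = lapse, snr = snr, n_channels = n_channels, sfreq = sfreq,
         epoch_window = epoch_window, noise_sd = noise_sd,
         nonresponse_rate = nonresponse_rate, artifact_rate = artifact_rate,
         workload_coupling = workload_coupling, task = task,
         master_seed = as.integer(master_seed)),
    class = "cohort_config"
  )
}

#' Simulate categorization behavior for a stimulus list
#'
#' A generative stand-in for the participant: on each trial the latent
#' category perception equals the true category with probability `p`; the
#' decision equals the perception unless a lapse flips it (probability
#' `lapse`) or the trial is a non-response. Reaction times are lognormal
#' with a lower median on correct trials, mimicking the reported
#' correct < incorrect RT pattern. Expected behavioral accuracy is
#' `p (1 - lapse) + (1 - p) lapse`.
#'
#' @param stimuli Tibble from [sample_stimuli()] (needs `trial`,
#'   `category`).
#' @param p Perceptual accuracy in (0,1).
#' @param lapse Decision lapse rate in `[0,1)`.
#' @param rng_seed Integer seed.
#' @param nonresponse_rate Probability of a simulated non-response
#'   (decision `NA`).
#' @param rt_median Named vector of RT medians (ms) for correct/incorrect
#'   trials.
#' @param rt_sdlog Lognormal sdlog for RTs.
#' @return Trial table tibble: `trial`, `true_category`, `mu_true`,
#'   `decision`, `correct`, `rt_ms`, `artifact` (initialized FALSE).
#' @export
simulate_behavior <- function(stimuli, p, lapse = 0, rng_seed = 1L,
                              nonresponse_rate = 0,
                              rt_median = c(correct = 470, incorrect = 520),
                              rt_sdlog = 0.25) {
  assert_prob(p, "p", open_high = FALSE) # p = 1 is the noise-free limit
  assert_prob(lapse, "lapse", open_low = FALSE)
  n <- nrow(stimuli)
  with_seed_(rng_seed, {
    nu <- as.integer(stimuli$category)
    flip_mu <- stats::runif(n) >= p
    mu <- ifelse(flip_mu, 3L - nu, nu)
    flip_d <- stats::runif(n) < lapse
    d <- ifelse(flip_d, 3L - mu, mu)
    nr <- stats::runif(n) < nonresponse_rate
    d[nr] <- NA_integer_
    correct <- !is.na(d) & d == nu
    med <- ifelse(correct, rt_median[["correct"]], rt_median[["incorrect"]])
    rt <- stats::rlnorm(n, meanlog = log(med), sdlog = rt_sdlog)
    rt[is.na(d)] <- NA_real_
    tibble::tibble(
      trial = stimuli$trial, true_category = nu, mu_true = as.integer(mu),
      decision = as.integer(d), correct = correct, rt_ms = rt,
      artifact = FALSE
    )
  })
}

# Smooth spatial covariance factor from the montage (used for background
# mixing and for smooth random topographies).
spatial_mixing <- function(positions, length_scale = 0.8) {
  d2 <- as.matrix(stats::dist(positions))^2
  k <- exp(-d2 / (2 * length_scale^2)) + diag(0.05, nrow(positions))
  e <- eigen(k, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
}

# 1/f amplitude-spectrum noise, one column per signal.
one_over_f_noise <- function(n_samples, n_signals) {
  nf <- n_samples %/% 2
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  spec <- matrix(0 + 0i, n_samples, n_signals)
  ph <- matrix(stats::runif(nf * n_signals, 0, 2 * pi), nf, n_signals)
  spec[f + 1L, ] <- amp * exp(1i * ph)
  idx_neg <- n_samples - f + 1L
  keep <- idx_neg > nf + 1L
  spec[idx_neg[keep], ] <- Conj(spec[f[keep] + 1L, ])
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / sqrt(n_samples)
  scale(x, center = TRUE, scale = apply(x, 2, stats::sd))
}

# ERP-like waveform: Hann bump supported on [300, 700] ms, unit peak.
erp_waveform <- function(times, support = c(300, 700)) {
  w <- numeric(length(times))
  inside <- times >= support[1] & times <= support[2]
  u <- (times[inside] - support[1]) / diff(support)
  w[inside] <- 0.5 * (1 - cos(2 * pi * u))
  w
}

# Two distinct unit-norm smooth topographies (second orthogonalized against
# the first so the classes are maximally distinguishable spatially).
perception_topographies <- function(positions, rng_seed) {
  with_seed_(rng_seed, {
    mix <- spatial_mixing(positions)
    a1 <- as.numeric(mix %*% stats::rnorm(nrow(positions)))
    a2 <- as.numeric(mix %*% stats::rnorm(nrow(positions)))
    a1 <- a1 / sqrt(sum(a1^2))
    a2 <- a2 - sum(a2 * a1) * a1
    a2 <- a2 / sqrt(sum(a2^2))
    list(a1, a2)
  })
}

#' Simulate EEG epochs carrying perception-state information
#'
#' Each epoch is spatially correlated 1/f background noise plus a
#' perception-specific component: a fixed unit-norm smooth topography (one
#' of two, selected by the trial's latent perception) times an ERP-like
#' waveform supported on 300--700 ms, with amplitude set by `snr` (see
#' [cohort_config()] for the amplitude convention). A random subset of
#' trials receives a large injected spike to emulate artifact
#' contamination; those trials are marked in the returned trial table's
#' `artifact` column (ground truth, distinct from downstream detection).
#'
#' @param trials Trial table from [simulate_behavior()].
#' @param cfg A [cohort_config()] (fields `snr`, `n_channels`, `sfreq`,
#'   `epoch_window`, `noise_sd`, `artifact_rate` are used).
#' @param rng_seed Integer seed; same seed gives bit-identical arrays.
#' @return An [epoch_set()] with the (updated) trial table attached.
#' @export
simulate_epochs <- function(trials, cfg, rng_seed = 1L) {
  if (cfg$n_channels < 4) stop("need at least 4 channels", call. = FALSE)
  if (cfg$snr < 0) stop("`snr` must be nonnegative", call. = FALSE)
  mont <- standard_montage(cfg$n_channels)
  pos <- as.matrix(mont[, c("x", "y", "z")])
  times <- default_times(cfg$sfreq, cfg$epoch_window)
  n_t <- nrow(trials)
  n_c <- cfg$n_channels
  n_s <- length(times)
  topo <- perception_topographies(pos, derive_seed(rng_seed, 101L))
  wave <- erp_waveform(times)
  # unit-norm topography: at the waveform peak the Euclidean norm of the
  # signal across the array equals 2 snr x the per-channel background RMS.
  # The factor 2 calibrates the snr dial so snr = 2 sits at the edge of
  # reliable single-trial decodability while single-channel amplitudes stay
  # at physiological ERP scale (~10-50 uV peaks).
  amp <- 2 * cfg$snr * cfg$noise_sd
  with_seed_(derive_seed(rng_seed, 102L), {
    mix <- spatial_mixing(pos)
    # normalize mixing rows so each channel has unit marginal variance
    mix <- mix / sqrt(rowSums(mix^2))
    data <- array(0, dim = c(n_t, n_c, n_s))
    for (t in seq_len(n_t)) {
      bg <- cfg$noise_sd * (mix %*% t(one_over_f_noise(n_s, n_c)))
      sig <- amp * tcrossprod(topo[[trials$mu_true[t]]], wave)
      data[t, , ] <- bg + sig
    }
    art <- stats::runif(n_t) < cfg$artifact_rate
    if (any(art)) {
      spike_len <- max(3L, round(0.05 * cfg$sfreq))
      for (t in which(art)) {
        ch <- sample.int(n_c, 1L)
        start <- sample.int(n_s - spike_len, 1L)
        data[t, ch, start:(start + spike_len - 1L)] <-
          data[t, ch, start:(start + spike_len - 1L)] +
          10 * cfg$noise_sd * 5 # 10x a typical 150 uV-scale excursion
      }
    }
    trials$artifact <- art
    epoch_set(data, cfg$sfreq, times, mont$channel, trials = trials)
  })
}

#' Simulate subjective workload scores coupled to the resource parameter
#'
#' `score = clip(intercept + slope * zeta_true + noise, 0, 1)`. A positive
#' slope yields a positive cohort correlation between workload and the
#' resource parameter (the direction reported for the rule-based task).
#'
#' @param zeta_true Numeric vector of per-participant true resource
#'   parameters.
#' @param coupling Named vector `c(intercept, slope, sd)`.
#' @param rng_seed Integer seed.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
simulate_workload <- function(zeta_true,
                              coupling = c(intercept = 0.55, slope = 0.1,
                                           sd = 0.03),
                              rng_seed = 1L) {
  stopifnot(is.finite(coupling[["slope"]]))
  with_seed_(rng_seed, {
    raw <- coupling[["intercept"]] + coupling[["slope"]] * zeta_true +
      stats::rnorm(length(zeta_true), 0, coupling[["sd"]])
    pmin(pmax(raw, 0), 1)
  })
}

# True resource parameter implied by the generative behavior settings:
# effective accuracy p(1-lapse) + (1-p)lapse under the balanced closed form.
true_zeta <- function(p, lapse = 0) {
  acc <- p * (1 - lapse) + (1 - p) * lapse
  -stats::qlogis(acc) / log(2)
}

#' Simulate one synthetic participant (behavior + EEG)
#'
#' @param cfg A [cohort_config()].
#' @param participant Participant index (used to derive seeds and, when
#'   `cfg$p` is a range, to draw the participant's accuracy).
#' @return List with `trials`, `epochs`, `p`, `zeta_true`, `workload`.
#' @export
simulate_participant <- function(cfg, participant = 1L) {
  seed_p <- derive_seed(cfg$master_seed, 1000L + participant)
  p_i <- if (length(cfg$p) == 2L) {
    with_seed_(derive_seed(seed_p, 1L), stats::runif(1, cfg$p[1], cfg$p[2]))
  } else cfg$p
  space <- category_space(cfg$task,
                          polarity = if (participant %% 2 == 0) "B" else "A")
  stim <- sample_stimuli(space, cfg$n_trials, derive_seed(seed_p, 2L))
  trials <- simulate_behavior(stim, p = p_i, lapse = cfg$lapse,
                              rng_seed = derive_seed(seed_p, 3L),
                              nonresponse_rate = cfg$nonresponse_rate)
  epochs <- simulate_epochs(trials, cfg, rng_seed = derive_seed(seed_p, 4L))
  zt <- true_zeta(p_i, cfg$lapse)
  wl <- simulate_workload(zt, cfg$workload_coupling,
                          rng_seed = derive_seed(seed_p, 5L))
  list(trials = epochs$trials, epochs = epochs, p = p_i, zeta_true = zt,
       workload = wl)
}
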