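test_that("band-pass removes DC and stop-band, preserves the pass-band", {
  sfreq <- 256
  times <- seq(-200, by = 1000 / sfreq, length.out = round(1.2 * sfreq))
  tsec <- times / 1000
  mk <- function(x) epoch_set(array(rep(x, each = 2), c(1, 2, length(x))),
                              sfreq, times, c("C3", "C4"))
  # DC input
  out <- bandpass_filter(mk(rep(5, length(times))))
  expect_lt(max(abs(out$data)), 0.5)
  # 10 Hz sinusoid preserved within 5% (measured away from the edges)
  mid <- seq(50, length(times) - 50)
  s10 <- sin(2 * pi * 10 * tsec)
  out10 <- bandpass_filter(mk(s10))
  expect_lt(max(abs(out10$data[1, 1, mid] - s10[mid])), 0.05)
  # 50 Hz reduced by >= 90%, evaluated on the designed response
  expect_lte(bandpass_response(50), 0.1)
  # >= 20 dB attenuation at 0 and 60 Hz
  expect_lte(bandpass_response(0), 0.1)
  expect_lte(bandpass_response(60), 0.1)
  s50 <- sin(2 * pi * 50 * tsec)
  out50 <- bandpass_filter(mk(s50))
  expect_lt(max(abs(out50$data[1, 1, mid])), 0.1)
  # invalid band
  expect_error(bandpass_filter(mk(s10), low = 0.1, high = 200), "Nyquist|sfreq")
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  ep <- make_test_epochs(3, 4, fill = 5)
  out <- baseline_correct(ep)
  expect_equal(max(abs(out$data)), 0)
  # baseline offset + post-stimulus step
  ep2 <- make_test_epochs(1, 2, fill = 2)
  ep2$data[, , ep2$times > 0] <- 2 + 3
  out2 <- baseline_correct(ep2)
  expect_equal(unique(as.vector(out2$data[, , ep2$times > 0])), 3)
  # random data: baseline-window mean is numerically zero
  ep3 <- make_test_epochs(5, 6, seed = 1)
  out3 <- baseline_correct(ep3)
  base <- apply(out3$data[, , out3$times <= 0, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-9)
  expect_error(baseline_correct(ep3, window = c(-5000, -4000)), "empty")
})

test_that("average reference removes the channel mean and is idempotent", {
  ep <- make_test_epochs(2, 2, seed = 2)
  ep$data[1, 1, ] <- 3
  ep$data[1, 2, ] <- 1
  out <- average_reference(ep)
  expect_equal(as.vector(out$data[1, 1, ]), rep(1, dim(ep)[3]))
  expect_equal(as.vector(out$data[1, 2, ]), rep(-1, dim(ep)[3]))
  expect_identical(out$reference, "average")
  # random data: per-sample channel mean ~ 0, and idempotence
  ep2 <- make_test_epochs(4, 8, seed = 3)
  o1 <- average_reference(ep2)
  expect_lt(max(abs(apply(o1$data, c(1, 3), mean))), 1e-9)
  o2 <- average_reference(o1)
  expect_lt(max(abs(o2$data - o1$data)), 1e-12)
})

test_that("artifact scoring flags exactly the threshold violations", {
  ep <- make_test_epochs(10, 4, seed = 4)
  expect_identical(sum(reject_artifacts(ep, Inf)$artifact_mask), 0L)
  ep$data[7, 2, 100] <- ep$data[7, 2, 100] + 500
  out <- reject_artifacts(ep, 200)
  expect_identical(which(out$artifact_mask), 7L)
  ep_all <- make_test_epochs(3, 2, fill = 0)
  ep_all$data[, , 1] <- 1000
  expect_error(reject_artifacts(ep_all, 200), "threshold")
  expect_error(reject_artifacts(ep, 0), "> 0")
})

test_that("channel interpolation reconstructs smooth fields", {
  # empty bad list is the identity
  ep <- make_test_epochs(2, 8, seed = 5)
  expect_identical(interpolate_channels(ep, character())$data, ep$data)
  # constant field: interpolated channel equals the constant
  ep2 <- make_test_epochs(2, 16, fill = 2)
  ep2$data[, 3, ] <- 99
  out2 <- interpolate_channels(ep2, ep2$channels[3])
  expect_equal(as.vector(out2$data[, 3, ]), rep(2, 2 * dim(ep2)[3]))
  # linear potential gradient across the scalp: within 10% at a central site
  pos <- neurofep:::montage_positions(standard_montage(32)$channel)
  field <- 2 + 0.8 * pos[, 1] + 0.5 * pos[, 2]
  ep3 <- make_test_epochs(1, 32, fill = 0)
  ep3$data[1, , ] <- field
  bad <- "C3"
  b_idx <- match(bad, ep3$channels)
  truth <- field[b_idx]
  ep3$data[1, b_idx, ] <- -50 # corrupted
  out3 <- interpolate_channels(ep3, bad)
  expect_lt(abs(out3$data[1, b_idx, 1] - truth) / abs(truth), 0.1)
  expect_error(interpolate_channels(ep3, ep3$channels), "all channels")
})

test_that("the epoch container round-trips through disk", {
  ep <- make_test_epochs(3, 4, seed = 6)
  ep$trials <- tibble::tibble(trial = 1:3, true_category = c(1L, 2L, 1L),
                              decision = c(1L, 2L, 2L))
  path <- withr::local_tempdir()
  write_epoch_set(ep, path)
  back <- read_epoch_set(path)
  expect_equal(back$data, ep$data, tolerance = 1e-6) # float32 storage
  expect_identical(back$channels, ep$channels)
  expect_equal(back$times, ep$times)
  expect_identical(back$trials$decision, ep$trials$decision)
})

test_that("the preprocessing runner enforces the published order", {
  cfg <- cohort_config(n_trials = 30, n_channels = 8, snr = 1,
                       artifact_rate = 0.1, master_seed = 9)
  stim <- sample_stimuli(category_space("II"), 30, rng_seed = 9)
  tr <- simulate_behavior(stim, p = 0.7, rng_seed = 9)
  ep <- simulate_epochs(tr, cfg, rng_seed = 9)
  out <- preprocess(ep)
  expect_identical(out$reference, "average")
  expect_false(any(out$artifact_mask))
  expect_lt(nrow(out$trials), nrow(tr)) # contaminated trials dropped
  base <- apply(out$data[, , out$times <= 0, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-9)
})
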