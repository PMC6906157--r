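test_that("whitening retains the expected rank and whitens exactly", {
  # white noise after average referencing: rank = channels - 1
  ep <- average_reference(make_test_epochs(40, 16, seed = 10))
  wh <- reduce_whiten(ep)
  expect_identical(wh$rank, 15L)
  # data confined to a 3-dimensional subspace
  ep3 <- make_test_epochs(20, 8, seed = 11)
  basis <- withr::with_seed(12, matrix(rnorm(8 * 3), 8, 3))
  for (t in 1:20) {
    ep3$data[t, , ] <- basis %*% matrix(rnorm(3 * dim(ep3)[3]), 3)
  }
  expect_identical(reduce_whiten(ep3)$rank, 3L)
  # transformed pooled covariance is the identity
  comp <- apply_transform(ep, wh)
  idx <- which(comp$times >= 0)
  pool <- matrix(0, wh$rank, wh$rank)
  for (t in 1:40) pool <- pool + tcrossprod(comp$data[t, , idx])
  pool <- pool / 40
  expect_lt(max(abs(pool - diag(wh$rank))), 1e-6)
})

test_that("the two-channel toy recovers lambda = 0.9/0.1 with axis filters", {
  toy <- make_csp_toy()
  m <- fit_csp(toy$epochs, toy$classes)
  expect_equal(sort(m$eigenvalues), c(0.1, 0.9), tolerance = 1e-8)
  # filters align with the channel axes (one zero entry per filter)
  for (i in 1:2) {
    w <- m$filters[i, ]
    expect_lt(min(abs(w)) / max(abs(w)), 1e-8)
  }
})

test_that("identical class covariances give lambda = 0.5 everywhere", {
  toy <- make_csp_toy()
  m <- fit_csp(toy$epochs, rep(1:2, times = 4)) # same trials in both classes
  expect_equal(m$eigenvalues, c(0.5, 0.5), tolerance = 1e-8)
})

test_that("fit_csp matches an independent generalized eigen-solver", {
  ep <- make_test_epochs(30, 6, seed = 13)
  classes <- rep(1:2, each = 15)
  withr::with_seed(14, {
    scale1 <- c(3, 1, 1.5, 0.5, 1, 2)
    for (t in 1:15) ep$data[t, , ] <- ep$data[t, , ] * scale1
  })
  m <- fit_csp(ep, classes)
  # oracle: same covariances, solved via eigen(solve(pool) %*% s1)
  idx <- which(ep$times >= 0)
  cov_of <- function(ts) {
    acc <- matrix(0, 6, 6)
    for (t in ts) {
      cc <- tcrossprod(ep$data[t, , idx])
      acc <- acc + cc / sum(diag(cc))
    }
    acc / length(ts)
  }
  s1 <- cov_of(1:15)
  pool <- s1 + cov_of(16:30)
  ev <- eigen(solve(pool) %*% s1)
  expect_equal(sort(m$eigenvalues), sort(Re(ev$values)), tolerance = 1e-8)
  # filters agree up to sign after matching normalization w' pool w = 1
  for (i in 1:6) {
    v <- Re(ev$vectors[, i])
    v <- v / sqrt(as.numeric(t(v) %*% pool %*% v))
    j <- which.min(abs(m$eigenvalues - Re(ev$values[i])))
    w <- m$filters[j, ]
    expect_lt(min(sum((w - v)^2), sum((w + v)^2)), 1e-12)
  }
  # model invariant: filters diagonalize the class covariances in pairs
  d1 <- diag(m$filters %*% s1 %*% t(m$filters))
  expect_equal(unname(d1), m$eigenvalues, tolerance = 1e-8)
})

test_that("log variance-share features behave per definition", {
  toy <- make_csp_toy()
  m <- fit_csp(toy$epochs, toy$classes)
  f <- extract_features(toy$epochs, m)
  fm <- neurofep:::feature_matrix(f)
  # normalization: sum(exp(f)) = 1 per trial
  expect_lt(max(abs(rowSums(exp(fm)) - 1)), 1e-9)
  # scale invariance
  ep_scaled <- toy$epochs
  ep_scaled$data <- ep_scaled$data * 7.3
  expect_equal(neurofep:::feature_matrix(extract_features(ep_scaled, m)),
               fm, tolerance = 1e-12)
  # N_rank = 1: the single feature is forced to log(1) = 0
  m1 <- m
  m1$filters <- m$filters[1, , drop = FALSE]
  m1$n_rank <- 1L
  f1 <- extract_features(toy$epochs, m1)
  expect_equal(unique(f1$f1), 0)
  # hand-computed two-trial, two-filter oracle
  ep2 <- epoch_set(array(c(1, 2, 2, 1, 5, 1, 0, 2), c(2, 2, 2)),
                   256, c(0, 1000 / 256), c("C3", "C4"))
  id <- structure(list(filters = diag(2), patterns = diag(2),
                       eigenvalues = c(0.5, 0.5), n_rank = 2L),
                  class = "csp_model")
  fh <- neurofep:::feature_matrix(extract_features(ep2, id))
  v11 <- var(ep2$data[1, 1, ]) # trial 1, filter 1
  v12 <- var(ep2$data[1, 2, ])
  expect_equal(unname(fh[1, 1]), log(v11 / (v11 + v12)), tolerance = 1e-12)
  expect_equal(unname(fh[1, 2]), log(v12 / (v11 + v12)), tolerance = 1e-12)
})

test_that("CSP separates synthetic perception classes and recovers patterns", {
  fx <- participant_fixture()
  fm <- neurofep:::feature_matrix(fx$features)
  mu <- fx$trials$mu_true
  # top-2 features linearly separate the perception classes (>= 90%)
  fit <- suppressWarnings(
    glm(I(mu == 1) ~ fm[, 1] + fm[, 2], family = binomial()))
  acc <- mean((fitted(fit) > 0.5) == (mu == 1))
  expect_gte(acc, 0.9)
  # leading pattern correlates with an injected topography (|r| >= 0.9)
  pos <- neurofep:::montage_positions(fx$clean$channels)
  topo <- neurofep:::perception_topographies(
    pos, neurofep:::derive_seed(neurofep:::derive_seed(
      neurofep:::derive_seed(77, 1001L), 4L), 101L))
  # patterns live in whitened component space; map back to channels
  lead <- fx$csp$patterns[, 1]
  wh <- reduce_whiten(fx$clean)
  chan_pattern <- as.numeric(MASS::ginv(wh$W) %*% lead)
  r <- max(abs(cor(chan_pattern, topo[[1]])), abs(cor(chan_pattern, topo[[2]])))
  expect_gte(r, 0.9)
})
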