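test_that("K-means clustering separates blobs and matches brute force", {
  blobs <- withr::with_seed(20, rbind(
    matrix(rnorm(20, mean = 0, sd = 0.3), 10, 2),
    matrix(rnorm(20, mean = 4, sd = 0.3), 10, 2)))
  cl <- cluster_perceptions(blobs, rng_seed = 1)
  expect_identical(length(unique(cl[1:10])), 1L)
  expect_identical(length(unique(cl[11:20])), 1L)
  expect_false(cl[1] == cl[11])
  # degenerate duplicated point set
  expect_error(cluster_perceptions(matrix(1, 6, 2), 1), "identical")
  # brute force over all 2-partitions of 14 points
  pts <- withr::with_seed(21, rbind(
    matrix(rnorm(14, 0, 0.8), 7, 2), matrix(rnorm(14, 3, 0.8), 7, 2)))
  wss <- function(assign) {
    s <- 0
    for (g in unique(assign)) {
      m <- colMeans(pts[assign == g, , drop = FALSE])
      s <- s + sum(sweep(pts[assign == g, , drop = FALSE], 2, m)^2)
    }
    s
  }
  best <- Inf
  best_assign <- NULL
  for (code in 1:(2^13 - 1)) { # fix point 1 in group 1, avoid empty groups
    assign <- c(1L, 1L + as.integer(intToBits(code)[1:13]))
    w <- wss(assign)
    if (w < best) {
      best <- w
      best_assign <- assign
    }
  }
  got <- cluster_perceptions(pts, rng_seed = 5)
  agree <- max(mean(got == best_assign), mean(got == 3L - best_assign))
  expect_equal(agree, 1)
  expect_equal(wss(got), best, tolerance = 1e-12)
})

test_that("cluster relabeling maximizes agreement with decisions", {
  m1 <- map_clusters_to_perceptions(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))
  expect_identical(m1$mu, c(1L, 1L, 2L, 2L))
  expect_equal(m1$agreement, 1)
  m2 <- map_clusters_to_perceptions(c(1L, 1L, 2L, 2L), c(2L, 2L, 1L, 1L))
  expect_identical(m2$mu, c(2L, 2L, 1L, 1L))
  expect_equal(m2$agreement, 1)
  # tie: both bijections give 0.5; identity mapping wins
  m3 <- map_clusters_to_perceptions(c(1L, 2L, 1L, 2L), c(1L, 1L, 2L, 2L))
  expect_identical(m3$mu, c(1L, 2L, 1L, 2L))
  expect_equal(m3$agreement, 0.5)
  # non-responses excluded from the agreement count
  m4 <- map_clusters_to_perceptions(c(1L, 1L, 2L), c(1L, 1L, NA))
  expect_equal(m4$agreement, 1)
})

test_that("stratified folds preserve class proportions", {
  labels <- rep(c(1L, 2L), c(40, 20))
  fold <- neurofep:::stratified_folds(labels, 10, 3)
  for (k in 1:10) {
    expect_identical(sum(labels == 1 & fold == k), 4L)
    expect_identical(sum(labels == 2 & fold == k), 2L)
  }
})

test_that("cross-validated posteriors are calibrated probability pairs", {
  # separable two-class features
  x <- withr::with_seed(30, rbind(
    matrix(rnorm(120, -2, 0.5), 60, 2), matrix(rnorm(120, 2, 0.5), 60, 2)))
  y <- rep(1:2, each = 60)
  post <- svm_cv_posteriors(x, y, sigma = 2, box = 1, rng_seed = 7)
  expect_lt(max(abs(post$p_nu1 + post$p_nu2 - 1)), 1e-9)
  expect_gte(mean(ifelse(y == 1, post$p_nu1, post$p_nu2)), 0.9)
  expect_gte(mean(post$predicted == y), 0.95)
  expect_error(svm_cv_posteriors(x[1:12, ], y[c(1:6, 61:66)], 2, 1,
                                 folds = 10), "folds")
})

test_that("hyperparameter tuning is seeded and tracks separability", {
  x <- withr::with_seed(31, rbind(
    matrix(rnorm(120, -2, 0.4), 60, 2), matrix(rnorm(120, 2, 0.4), 60, 2)))
  y <- rep(1:2, each = 60)
  t1 <- tune_svm(x, y, rng_seed = 11, budget = 10)
  t2 <- tune_svm(x, y, rng_seed = 11, budget = 10)
  expect_identical(t1, t2)
  expect_lte(t1$cv_error, 0.05) # easy wide-margin problem
  # pure-noise labels: optimum stays near chance
  yn <- withr::with_seed(32, sample(rep(1:2, each = 100)))
  xn <- withr::with_seed(33, matrix(rnorm(400), 200, 2))
  tn <- tune_svm(xn, yn, rng_seed = 12, budget = 10)
  expect_gte(tn$cv_error, 0.3)
  expect_lte(tn$cv_error, 0.6)
  expect_warning(tune_svm(x, y, rng_seed = 1, budget = 3), "budget")
})

test_that("recognition rows average posteriors per perception group", {
  post <- tibble::tibble(p_nu1 = c(0.8, 0.6, 1, 0.3),
                         p_nu2 = c(0.2, 0.4, 0, 0.7),
                         predicted = c(1L, 1L, 1L, 2L))
  q <- estimate_recognition(post, c(1L, 1L, 2L, 2L))
  expect_equal(unname(q[1, ]), c(0.7, 0.3))
  expect_equal(unname(q[2, ]), c(0.65, 0.35))
  expect_lt(max(abs(rowSums(q) - 1)), 1e-9)
  expect_error(estimate_recognition(post, c(1L, 1L, 1L, 1L)), "empty")
  # all-uniform posteriors give the uniform recognition matrix
  pu <- tibble::tibble(p_nu1 = rep(0.5, 4), p_nu2 = rep(0.5, 4),
                       predicted = rep(1L, 4))
  expect_equal(unname(estimate_recognition(pu, c(1L, 2L, 1L, 2L))),
               matrix(0.5, 2, 2))
})

test_that("repeat averaging is deterministic and reduces to one repeat", {
  fx <- participant_fixture()
  r1 <- repeat_and_average(fx$features, fx$trials, sigma = 10, box = 1,
                           n_repeats = 3, rng_seed = 42)
  r2 <- repeat_and_average(fx$features, fx$trials, sigma = 10, box = 1,
                           n_repeats = 3, rng_seed = 42)
  expect_identical(r1$Q, r2$Q)
  expect_identical(r1$per_trial_mu, r2$per_trial_mu)
  # n_repeats = 1 equals a single manually assembled estimate
  rs <- neurofep:::derive_seed(42, 1L)
  cl <- cluster_perceptions(fx$features, neurofep:::derive_seed(rs, 1L))
  mp <- map_clusters_to_perceptions(cl, fx$trials$decision)
  post <- svm_cv_posteriors(fx$features, fx$trials$true_category, 10, 1,
                            rng_seed = neurofep:::derive_seed(rs, 2L))
  q_single <- estimate_recognition(post, mp$mu)
  one <- repeat_and_average(fx$features, fx$trials, sigma = 10, box = 1,
                            n_repeats = 1, rng_seed = 42)
  expect_equal(one$Q, q_single)
})

test_that("the averaged Q tracks the perception-category agreement", {
  fx <- participant_fixture()
  tuned <- tune_svm(fx$features, fx$trials$true_category, rng_seed = 3,
                    budget = 15)
  recog <- repeat_and_average(fx$features, fx$trials, sigma = tuned$sigma,
                              box = tuned$box, n_repeats = 10,
                              rng_seed = 8)
  expect_lt(max(abs(rowSums(recog$Q) - 1)), 1e-9)
  # ground-truth confusion: how often does perception match the category?
  agree <- mean(fx$trials$mu_true == fx$trials$true_category)
  q_match <- mean(c(recog$Q[1, 1], recog$Q[2, 2]))
  expect_lt(abs(q_match - agree), 0.1)
  # the recovered perception index matches the injected one (snr = 2)
  rec <- max(mean(recog$per_trial_mu == fx$trials$mu_true),
             mean(3L - recog$per_trial_mu == fx$trials$mu_true))
  expect_gte(rec, 0.9)
})
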