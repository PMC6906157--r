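test_that("GFP is the population across-channel SD of the ERP", {
  ep <- make_test_epochs(4, 3, fill = 2)
  g <- erp_gfp(ep, rep("all", 4))
  expect_true(all(g$gfp$gfp == 0))
  # two channels at +a/-a
  a <- 1.7
  ep2 <- make_test_epochs(2, 2, fill = 0)
  ep2$data[, 1, ] <- a
  ep2$data[, 2, ] <- -a
  g2 <- erp_gfp(ep2, rep("x", 2))
  expect_equal(unique(g2$gfp$gfp), a)
  # homogeneity: scaling channels scales GFP
  ep3 <- make_test_epochs(3, 6, seed = 60)
  g3 <- erp_gfp(ep3, rep("x", 3))
  ep3$data <- ep3$data * 3
  g3s <- erp_gfp(ep3, rep("x", 3))
  expect_equal(g3s$gfp$gfp, 3 * g3$gfp$gfp, tolerance = 1e-12)
})

test_that("max-statistic test finds nothing when waveforms are identical", {
  w <- withr::with_seed(61, matrix(rnorm(10 * 40), 10, 40))
  res <- pointwise_maxstat_ttest(w, w, n_perm = 200, rng_seed = 1)
  expect_false(any(res$result$significant))
  # p resolution with few permutations
  res10 <- pointwise_maxstat_ttest(w + withr::with_seed(62,
    matrix(rnorm(400, 0, 0.1), 10, 40)), w, n_perm = 10, rng_seed = 2)
  expect_gte(min(res10$result$p_corrected), 1 / 11)
})

test_that("max-statistic test localizes a strong injected difference", {
  withr::with_seed(63, {
    a <- matrix(rnorm(12 * 80), 12, 80)
    b <- matrix(rnorm(12 * 80), 12, 80)
  })
  window <- 30:40
  a[, window] <- a[, window] + 3
  res <- pointwise_maxstat_ttest(a, b, n_perm = 500, rng_seed = 3)
  sig <- which(res$result$significant)
  expect_true(all(sig %in% window))
  expect_gte(length(sig), 5)
})

test_that("RM-ANOVA F values match the base-R aov decomposition", {
  withr::with_seed(65, {
    v1 <- matrix(rnorm(12 * 3, sd = 1), 12, 3) +
      matrix(c(0, 0.5, 1), 12, 3, byrow = TRUE)
  })
  design <- factor(c("a", "b", "c"))
  got <- perm_rm_anova(v1, design, n_perm = 50, rng_seed = 1)
  df <- data.frame(y = as.vector(v1),
                   cond = design[rep(1:3, each = 12)],
                   subj = factor(rep(1:12, 3)))
  oracle <- summary(aov(y ~ cond + Error(subj/cond), data = df))
  f_oracle <- oracle[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(got$result$statistic, f_oracle, tolerance = 1e-8)
  # two-way within design
  withr::with_seed(66, v2 <- matrix(rnorm(10 * 4), 10, 4))
  d2 <- data.frame(task = factor(c("II", "II", "RB", "RB")),
                   state = factor(c("m", "mm", "m", "mm")))
  got2 <- perm_rm_anova(v2, d2, n_perm = 50, rng_seed = 2)
  df2 <- data.frame(y = as.vector(v2),
                    task = d2$task[rep(1:4, each = 10)],
                    state = d2$state[rep(1:4, each = 10)],
                    subj = factor(rep(1:10, 4)))
  or2 <- summary(aov(y ~ task * state + Error(subj / (task * state)),
                     data = df2))
  expect_equal(got2$result$statistic[got2$result$effect == "task"],
               or2[["Error: subj:task"]][[1]]["task", "F value"],
               tolerance = 1e-8)
  expect_equal(got2$result$statistic[got2$result$effect == "state"],
               or2[["Error: subj:state"]][[1]]["state", "F value"],
               tolerance = 1e-8)
  expect_equal(got2$result$statistic[got2$result$effect == "task:state"],
               or2[["Error: subj:task:state"]][[1]]["task:state", "F value"],
               tolerance = 1e-8)
})

test_that("identical condition columns give a null effect", {
  v <- withr::with_seed(67, matrix(rnorm(8), 8, 1))[, c(1, 1)]
  got <- perm_rm_anova(v, factor(c("a", "b")), n_perm = 100, rng_seed = 1)
  expect_gte(got$result$p_value, 0.99)
  expect_equal(got$result$eta_sq_partial, 0)
})

test_that("two-condition permutation p agrees with exhaustive enumeration", {
  withr::with_seed(68, {
    v <- cbind(rnorm(10), rnorm(10) + 0.8)
  })
  d <- v[, 1] - v[, 2]
  t_sq <- function(x) {
    length(x) * mean(x)^2 / var(x)
  }
  f_obs <- t_sq(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  f_all <- apply(signs, 1, function(s) t_sq(s * d))
  p_exact <- mean(f_all >= f_obs - 1e-12)
  got <- perm_rm_anova(v, factor(c("a", "b")), n_perm = 5000, rng_seed = 4)
  expect_lt(abs(got$result$p_value - p_exact), 0.01)
})

test_that("randomization correlations behave at the extremes and the null", {
  x <- withr::with_seed(70, rnorm(30))
  res <- randomization_corr(x, x, n_rand = 200, rng_seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 1 / 201)
  resn <- randomization_corr(x, -x, n_rand = 200, rng_seed = 1)
  expect_equal(resn$r, -1)
  expect_error(randomization_corr(x, rep(1, 30)), "variance")
  expect_error(randomization_corr(x[1:3], x[1:3]), "4")
  # null calibration: p values approximately uniform
  ps <- withr::with_seed(71, {
    vapply(seq_len(1000), function(i) {
      randomization_corr(rnorm(20), rnorm(20), n_rand = 199,
                         rng_seed = i)$p_value
    }, numeric(1))
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("BH-FDR matches the brute-force step-up definition", {
  expect_identical(fdr_bh(c(0.001, 0.02, 0.04, 0.2), q = 0.05), c(1L, 2L))
  expect_identical(fdr_bh(rep(1, 5)), integer(0))
  expect_identical(fdr_bh(numeric(0)), integer(0))
  brute_bh <- function(p, q) {
    m <- length(p)
    o <- order(p)
    k <- 0
    for (i in seq_len(m)) if (p[o[i]] <= i * q / m) k <- i
    if (k == 0) integer(0) else sort(o[seq_len(k)])
  }
  withr::with_seed(72, {
    for (rep in 1:50) {
      p <- runif(3)
      expect_identical(sort(fdr_bh(p, 0.05)), brute_bh(p, 0.05))
    }
  })
})
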