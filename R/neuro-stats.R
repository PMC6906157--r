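# ERP/GFP computation and the permutation/randomization statistics battery.

#' ERP and global field power per trial group
#'
#' For each group of trials: the ERP is the trial mean per channel and time
#' point; evoked GFP is the across-channel standard deviation of the ERP at
#' each time point (population form, so two channels at +a/-a give GFP a).
#'
#' @param epochs An [epoch_set()] with at least 2 channels.
#' @param groups Factor/vector of group labels per trial (NA = excluded).
#' @return Object of class `gfp_result`: `gfp` tibble (`group`, `time`,
#'   `gfp`), `erp` named list of channels x time matrices, `times`.
#' @export
erp_gfp <- function(epochs, groups) {
  stopifnot(inherits(epochs, "epoch_set"),
            length(groups) == n_trials(epochs))
  if (dim(epochs$data)[2] < 2) stop("need >= 2 channels", call. = FALSE)
  groups <- as.factor(groups)
  lv <- levels(droplevels(groups))
  erp <- list()
  rows <- list()
  for (g in lv) {
    idx <- which(!is.na(groups) & groups == g)
    if (length(idx) == 0) stop(sprintf("group '%s' is empty", g),
                               call. = FALSE)
    e <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
    erp[[g]] <- e
    rows[[g]] <- tibble::tibble(group = g, time = epochs$times,
                                gfp = pop_sd_cols(e))
  }
  structure(list(gfp = dplyr::bind_rows(rows), erp = erp,
                 times = epochs$times),
            class = "gfp_result")
}

#' Pointwise paired t-tests with max-statistic correction
#'
#' Paired comparison of two per-participant waveforms at every time point.
#' The null distribution is built by randomly sign-flipping each
#' participant's difference waveform; the maximum absolute t across time
#' per permutation yields a familywise-error-controlling threshold at the
#' `1 - alpha` quantile.
#'
#' @param wave_a,wave_b Participants x time matrices (paired rows).
#' @param n_perm Number of permutations (p resolution is
#'   `1/(n_perm + 1)`).
#' @param alpha Two-tailed familywise alpha.
#' @param rng_seed Integer seed.
#' @return Object of class `maxstat_test`: tibble `result` (`time_index`,
#'   `t`, `p_corrected`, `significant`), plus `threshold`, `n_perm`,
#'   `alpha`.
#' @export
pointwise_maxstat_ttest <- function(wave_a, wave_b, n_perm = 5000,
                                    alpha = 0.05, rng_seed = 1L) {
  stopifnot(all(dim(wave_a) == dim(wave_b)))
  n <- nrow(wave_a)
  if (n < 6) warning("fewer than 6 participants: low power")
  d <- wave_a - wave_b
  t_obs <- paired_t_cols(d)
  nullmax <- with_seed_(rng_seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    m <- signs %*% d / n
    ss <- matrix(colSums(d^2), n_perm, ncol(d), byrow = TRUE)
    v <- (ss - n * m^2) / (n - 1)
    tmat <- m / sqrt(pmax(v, 1e-300) / n)
    apply(abs(tmat), 1, max)
  })
  threshold <- stats::quantile(nullmax, 1 - alpha, type = 1, names = FALSE)
  p_corr <- vapply(abs(t_obs), function(tj) {
    (1 + sum(nullmax >= tj)) / (n_perm + 1)
  }, numeric(1))
  structure(
    list(result = tibble::tibble(time_index = seq_along(t_obs), t = t_obs,
                                 p_corrected = p_corr,
                                 significant = abs(t_obs) > threshold),
         threshold = threshold, n_perm = n_perm, alpha = alpha),
    class = "maxstat_test"
  )
}

paired_t_cols <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  m / sqrt(pmax(v, 1e-300) / n)
}

# Effect F and partial eta-squared with guards for degenerate (zero
# sum-of-squares) inputs.
f_eta <- function(ss_eff, ss_err, df1, df2) {
  if (ss_eff <= 1e-300) {
    list(F = 0, df1 = df1, df2 = df2, eta = 0)
  } else {
    list(F = (ss_eff / df1) / (max(ss_err, 1e-300) / df2),
         df1 = df1, df2 = df2, eta = ss_eff / (ss_eff + ss_err))
  }
}

# Repeated-measures sums of squares for a fully within-subject design.
# values: participants x conditions; design: data frame of factors, one row
# per condition column.
rm_anova_F <- function(values, design) {
  n <- nrow(values)
  g <- mean(values)
  subj <- rowMeans(values)
  ss_subj <- ncol(values) * sum((subj - g)^2)
  ss_tot <- sum((values - g)^2)
  out <- list()
  if (ncol(design) == 1L) {
    f1 <- design[[1]]
    cm <- tapply(colMeans(values), f1, mean)
    reps <- table(f1)[names(cm)]
    ss_c <- n * sum(reps * (cm - g)^2)
    ss_err <- ss_tot - ss_subj - ss_c
    df1 <- nlevels(f1) - 1L
    df2 <- (n - 1L) * df1
    out[[names(design)[1]]] <- f_eta(ss_c, ss_err, df1, df2)
  } else {
    fa <- design[[1]]
    fb <- design[[2]]
    a <- nlevels(fa)
    b <- nlevels(fb)
    # cell means per subject x factor level
    mA <- t(apply(values, 1, function(r) tapply(r, fa, mean))) # n x a
    mB <- t(apply(values, 1, function(r) tapply(r, fb, mean))) # n x b
    gA <- colMeans(mA)
    gB <- colMeans(mB)
    cellAB <- tapply(colMeans(values), list(fa, fb), mean) # a x b
    ss_A <- n * b * sum((gA - g)^2)
    ss_B <- n * a * sum((gB - g)^2)
    ss_AB <- n * sum((cellAB - outer(gA - g, gB - g, "+") - g)^2)
    ss_As <- b * sum((mA - matrix(subj, n, a) -
                        matrix(gA, n, a, byrow = TRUE) + g)^2)
    ss_Bs <- a * sum((mB - matrix(subj, n, b) -
                        matrix(gB, n, b, byrow = TRUE) + g)^2)
    ss_ABs <- ss_tot - ss_subj - ss_A - ss_B - ss_AB - ss_As - ss_Bs
    dfs <- list(A = a - 1L, B = b - 1L, AB = (a - 1L) * (b - 1L))
    ss_eff <- list(A = ss_A, B = ss_B, AB = ss_AB)
    ss_er <- list(A = ss_As, B = ss_Bs, AB = ss_ABs)
    nm <- c(names(design)[1], names(design)[2],
            paste(names(design), collapse = ":"))
    for (i in 1:3) {
      key <- c("A", "B", "AB")[i]
      df1 <- dfs[[key]]
      df2 <- (n - 1L) * df1
      out[[nm[i]]] <- f_eta(ss_eff[[key]], max(ss_er[[key]], 0), df1, df2)
    }
  }
  out
}

#' Permutation repeated-measures ANOVA
#'
#' Observed F and partial eta-squared come from the standard
#' repeated-measures decomposition; the p-value is the proportion of
#' permutations (random reassignment of condition labels within each
#' participant) whose F meets or exceeds the observed one, with add-one
#' smoothing, so `p >= 1/(n_perm + 1)`. For a one-way two-condition design
#' the within-participant label swap is equivalent to sign-flipping the
#' paired differences and is computed vectorized.
#'
#' @param values Participants x conditions matrix (complete data).
#' @param design Either a factor of length `ncol(values)` (one-way) or a
#'   data frame of two factors (two-way, fully within).
#' @param n_perm Number of permutations.
#' @param rng_seed Integer seed.
#' @return Object of class `perm_anova`: tibble with one row per effect
#'   (`effect`, `df1`, `df2`, `statistic`, `p_value`, `eta_sq_partial`),
#'   plus `n_perm` and `seed`.
#' @export
perm_rm_anova <- function(values, design, n_perm = 5000, rng_seed = 1L) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells are not supported", call. = FALSE)
  if (!is.data.frame(design)) design <- data.frame(condition = factor(design))
  design[] <- lapply(design, function(f) droplevels(as.factor(f)))
  if (nrow(design) != ncol(values)) {
    stop("`design` must describe the condition columns", call. = FALSE)
  }
  obs <- rm_anova_F(values, design)
  n <- nrow(values)
  J <- ncol(values)
  exceed <- stats::setNames(numeric(length(obs)), names(obs))
  if (ncol(design) == 1L && J == 2L) {
    d <- values[, 1] - values[, 2]
    f_obs <- paired_t_col_sq(d)
    f_perm <- with_seed_(rng_seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                      n_perm, n)
      m <- as.numeric(signs %*% d) / n
      v <- (sum(d^2) - n * m^2) / (n - 1)
      n * m^2 / pmax(v, 1e-300)
    })
    exceed[1] <- sum(f_perm >= f_obs - 1e-12)
  } else {
    exceed[] <- with_seed_(rng_seed, {
      cnt <- numeric(length(obs))
      for (r in seq_len(n_perm)) {
        vp <- t(apply(values, 1, sample))
        fp <- rm_anova_F(vp, design)
        for (i in seq_along(obs)) {
          if (fp[[i]]$F >= obs[[i]]$F - 1e-12) cnt[i] <- cnt[i] + 1
        }
      }
      cnt
    })
  }
  res <- tibble::tibble(
    effect = names(obs),
    df1 = unname(vapply(obs, function(o) as.numeric(o$df1), numeric(1))),
    df2 = unname(vapply(obs, function(o) as.numeric(o$df2), numeric(1))),
    statistic = unname(vapply(obs, function(o) o$F, numeric(1))),
    p_value = unname((1 + exceed) / (n_perm + 1)),
    eta_sq_partial = unname(vapply(obs, function(o) o$eta, numeric(1)))
  )
  structure(list(result = res, n_perm = n_perm, seed = rng_seed),
            class = "perm_anova")
}

paired_t_col_sq <- function(d) {
  n <- length(d)
  m <- mean(d)
  v <- (sum(d^2) - n * m^2) / (n - 1)
  n * m^2 / pmax(v, 1e-300)
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf("<perm_anova> %d permutations\n", x$n_perm))
  print(as.data.frame(x$result))
  invisible(x)
}

#' Randomization test of a Pearson correlation
#'
#' Observed Pearson r; two-tailed p from shuffling `y` against `x`, with
#' add-one smoothing.
#'
#' @param x,y Numeric vectors of equal length (>= 4), nonzero variance.
#' @param n_rand Number of randomizations.
#' @param rng_seed Integer seed.
#' @return Object of class `randomization_corr`: `r`, `p_value`, `n`,
#'   `n_rand`, `seed`.
#' @export
randomization_corr <- function(x, y, n_rand = 5000, rng_seed = 1L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  r_obs <- stats::cor(x, y)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  r_null <- with_seed_(rng_seed, {
    vapply(seq_len(n_rand), function(i) {
      sum(xs * ys[sample.int(length(ys))]) / (length(x) - 1)
    }, numeric(1))
  })
  p <- (1 + sum(abs(r_null) >= abs(r_obs) - 1e-12)) / (n_rand + 1)
  structure(list(r = r_obs, p_value = p, n = length(x), n_rand = n_rand,
                 seed = rng_seed),
            class = "randomization_corr")
}

#' @export
print.randomization_corr <- function(x, ...) {
  cat(sprintf("<randomization_corr> r = %.3f, p = %.4f (n = %d, %d randomizations)\n",
              x$r, x$p_value, x$n, x$n_rand))
  invisible(x)
}

#' Benjamini-Hochberg FDR rejection set
#'
#' Step-up procedure controlling the false discovery rate at level `q`:
#' rejects the k smallest p-values where k is the largest i with
#' `p_(i) <= i q / m`.
#'
#' @param p_values Numeric p-values in (0, 1].
#' @param q FDR level.
#' @return Integer indices (into `p_values`) of the rejected hypotheses.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(integer(0))
  stopifnot(all(p_values > 0 & p_values <= 1))
  which(stats::p.adjust(p_values, method = "BH") <= q)
}
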