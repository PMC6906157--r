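# CSP feature extraction: PCA whitening (conditioning stand-in for the ICA
# decomposition step), common spatial pattern fitting via the generalized
# eigenproblem, and log variance-share feature vectors.

# Per-trial covariance over the post-stimulus window, averaged within a
# trial set; trace normalization (used for CSP class covariances) removes
# between-trial amplitude differences.
class_covariance <- function(epochs, idx_trials, idx_time,
                             normalize = TRUE) {
  n_c <- dim(epochs$data)[2]
  acc <- matrix(0, n_c, n_c)
  for (t in idx_trials) {
    x <- epochs$data[t, , idx_time, drop = TRUE]
    cc <- tcrossprod(x)
    acc <- acc + if (normalize) cc / sum(diag(cc)) else cc
  }
  acc / length(idx_trials)
}

poststim_index <- function(epochs) which(epochs$times >= 0)

#' Dimensionality reduction and whitening
#'
#' Computes a whitening linear map from the pooled (all-trial) covariance of
#' the post-stimulus interval, retaining the leading principal components
#' that explain at least `variance_fraction` of pooled variance. The output
#' rank defines the dimensionality of the downstream CSP model. PCA
#' whitening is the default conditioning step; its purpose is to remove
#' data interdependencies and near-null directions (such as the one
#' introduced by average referencing) before covariance estimation.
#'
#' @param epochs An [epoch_set()].
#' @param variance_fraction Fraction of pooled variance to retain.
#' @return An object of class `whitener`: list with `W` (rank x channels
#'   map), `rank`, `eigenvalues`.
#' @export
reduce_whiten <- function(epochs, variance_fraction = 0.99) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_trials(epochs) < 2) stop("need >= 2 trials", call. = FALSE)
  cov_pool <- class_covariance(epochs, seq_len(n_trials(epochs)),
                               poststim_index(epochs), normalize = FALSE)
  e <- eigen(cov_pool, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  tol <- max(ev) * 1e-9
  cum <- cumsum(ev) / sum(ev)
  rank <- max(which(cum < variance_fraction), 0L) + 1L
  rank <- min(rank, sum(ev > tol))
  if (rank < 2) stop("input is rank deficient (< 2 components)", call. = FALSE)
  keep <- seq_len(rank)
  W <- diag(1 / sqrt(ev[keep]), rank) %*% t(e$vectors[, keep, drop = FALSE])
  structure(list(W = W, rank = rank, eigenvalues = ev[keep]),
            class = "whitener")
}

#' Apply a linear channel transform to epochs
#'
#' @param epochs An [epoch_set()].
#' @param transform A `whitener` (or any list with a `W` matrix).
#' @return An [epoch_set()] in component space.
#' @export
apply_transform <- function(epochs, transform) {
  W <- transform$W
  d <- dim(epochs$data)
  out <- array(0, dim = c(d[1], nrow(W), d[3]))
  for (t in seq_len(d[1])) {
    out[t, , ] <- W %*% epochs$data[t, , , drop = TRUE]
  }
  e2 <- epochs
  e2$data <- out
  e2$channels <- paste0("comp", seq_len(nrow(W)))
  e2
}

#' Fit a common spatial patterns model
#'
#' Estimates, per perception class, the trial-averaged trace-normalized
#' covariance over the post-stimulus interval, then solves the generalized
#' eigenproblem `Sigma1 w = lambda (Sigma1 + Sigma2) w`. Filters (rows of
#' `filters`) are returned sorted by discriminability `max(lambda, 1 -
#' lambda)`; `patterns` holds the corresponding topographies (columns).
#'
#' @param epochs An [epoch_set()], typically already reduced/whitened.
#' @param classes Integer vector (1/2) of perception classes per trial;
#'   trials with `NA` are ignored.
#' @return An object of class `csp_model` with `filters`, `patterns`,
#'   `eigenvalues`, `n_rank`.
#' @export
fit_csp <- function(epochs, classes) {
  stopifnot(inherits(epochs, "epoch_set"),
            length(classes) == n_trials(epochs))
  i1 <- which(!is.na(classes) & classes == 1)
  i2 <- which(!is.na(classes) & classes == 2)
  if (length(i1) == 0 || length(i2) == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  ts_idx <- poststim_index(epochs)
  s1 <- class_covariance(epochs, i1, ts_idx)
  s2 <- class_covariance(epochs, i2, ts_idx)
  pool <- s1 + s2
  ep <- eigen(pool, symmetric = TRUE)
  if (min(ep$values) < max(ep$values) * 1e-10) {
    stop("pooled covariance is singular; reduce/whiten the data first",
         call. = FALSE)
  }
  pool_isqrt <- ep$vectors %*% diag(1 / sqrt(ep$values), length(ep$values)) %*%
    t(ep$vectors)
  es <- eigen(pool_isqrt %*% s1 %*% pool_isqrt, symmetric = TRUE)
  lambda <- pmin(pmax(es$values, 0), 1)
  ord <- order(pmax(lambda, 1 - lambda), decreasing = TRUE)
  filters <- t(es$vectors[, ord, drop = FALSE]) %*% pool_isqrt
  patterns <- pool %*% t(filters) # since filters %*% pool %*% t(filters) = I
  structure(
    list(filters = filters, patterns = patterns, eigenvalues = lambda[ord],
         n_rank = length(lambda),
         class_definitions = c("perception 1", "perception 2")),
    class = "csp_model"
  )
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d spatial filters; top eigenvalue %.3f\n",
              x$n_rank, x$eigenvalues[1]))
  invisible(x)
}

#' Extract log variance-share CSP features
#'
#' For each trial, projects the post-stimulus interval onto every CSP
#' filter, computes the variance of each activation time course, and
#' returns `f_i = log(var(Z_i) / sum_i var(Z_i))`. All `n_rank` filters
#' contribute, so `sum(exp(f_i)) = 1` per trial and the features are
#' invariant to rescaling an epoch.
#'
#' @param epochs An [epoch_set()] in the same channel/component space the
#'   model was fitted on.
#' @param model A [fit_csp()] model.
#' @return A tibble with `trial` and feature columns `f1..fN`.
#' @export
extract_features <- function(epochs, model) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(model, "csp_model"))
  if (ncol(model$filters) != dim(epochs$data)[2]) {
    stop("model was fitted on a different channel space", call. = FALSE)
  }
  ts_idx <- poststim_index(epochs)
  n_t <- n_trials(epochs)
  vals <- matrix(0, n_t, model$n_rank)
  for (t in seq_len(n_t)) {
    z <- model$filters %*% epochs$data[t, , ts_idx, drop = TRUE]
    v <- apply(z, 1, stats::var)
    tot <- sum(v)
    if (tot <= 0) stop(sprintf("trial %d has zero variance", t),
                       call. = FALSE)
    vals[t, ] <- log(v / tot)
  }
  colnames(vals) <- paste0("f", seq_len(model$n_rank))
  out <- tibble::as_tibble(vals)
  out$trial <- if (!is.null(epochs$trials) && "trial" %in% names(epochs$trials))
    epochs$trials$trial else seq_len(n_t)
  out[, c("trial", paste0("f", seq_len(model$n_rank)))]
}

# Feature tibble -> plain matrix of feature columns.
feature_matrix <- function(features) {
  as.matrix(features[, grep("^f[0-9]+$", names(features)), drop = FALSE])
}
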