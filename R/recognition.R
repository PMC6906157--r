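# Recognition-distribution estimation: K-means perception indexing,
# behavior-anchored cluster relabeling, stratified-CV RBF-SVM posteriors
# with Platt-style sigmoid calibration, and repeat averaging.

#' Cluster trials into two perception states
#'
#' Euclidean K-means (k = 2) on the CSP feature vectors with random
#' centroid initialization; the converged assignment is returned.
#'
#' @param features Feature tibble from [extract_features()] (or any numeric
#'   matrix).
#' @param rng_seed Integer seed for the centroid initialization.
#' @return Integer vector of cluster labels (1/2) per trial.
#' @export
cluster_perceptions <- function(features, rng_seed = 1L) {
  x <- if (is.data.frame(features)) feature_matrix(features) else
    as.matrix(features)
  if (nrow(x) < 2) stop("need >= 2 trials", call. = FALSE)
  if (all(apply(x, 2, function(v) diff(range(v)) == 0))) {
    stop("all feature vectors are identical; cannot cluster", call. = FALSE)
  }
  km <- with_seed_(rng_seed, stats::kmeans(x, centers = 2L))
  as.integer(km$cluster)
}

#' Map clusters to perception states via behavioral decisions
#'
#' Of the two possible cluster-to-perception bijections, chooses the one
#' that maximizes agreement with the behavioral decisions (non-response
#' trials excluded from the agreement count); ties map cluster 1 to
#' perception 1. This anchors the unsupervised cluster labels to the
#' participant's reported category perceptions.
#'
#' @param clusters Integer cluster labels (1/2) per trial.
#' @param decisions Integer decisions (1/2, `NA` for non-responses),
#'   aligned with `clusters`.
#' @return List with `mu` (perception index per trial) and `agreement`
#'   (achieved fraction, in `[0.5, 1]` over responded trials).
#' @export
map_clusters_to_perceptions <- function(clusters, decisions) {
  stopifnot(length(clusters) == length(decisions))
  resp <- !is.na(decisions)
  agree_id <- mean(clusters[resp] == decisions[resp])
  agree_sw <- mean((3L - clusters[resp]) == decisions[resp])
  if (agree_id >= agree_sw) {
    list(mu = as.integer(clusters), agreement = agree_id)
  } else {
    list(mu = as.integer(3L - clusters), agreement = agree_sw)
  }
}

# Stratified fold assignment: class proportions preserved per fold.
stratified_folds <- function(labels, folds, rng_seed) {
  with_seed_(rng_seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  })
}

# RBF-SVM decision values for a test set, trained on (x, y). sigma is a
# MATLAB-style kernel scale (gamma = 1/sigma^2); box is the penalty bound
# (cost). Positive decision values favor class 1 (fixed factor levels).
svm_decision_values <- function(x_train, y_train, x_test, sigma, box) {
  fit <- e1071::svm(x_train, factor(y_train, levels = c(1, 2)),
                    kernel = "radial", gamma = 1 / sigma^2, cost = box,
                    scale = FALSE)
  dv <- attr(stats::predict(fit, x_test, decision.values = TRUE),
             "decision.values")
  pos_class <- as.integer(sub("/.*", "", colnames(dv)[1]))
  if (pos_class == 1L) dv[, 1] else -dv[, 1]
}

# One CV fold: posterior pairs for the held-out trials via a Platt-style
# sigmoid calibrated on the training folds. The calibration decision
# values are themselves obtained by an internal cross-validation within
# the training folds -- calibrating on the training fit's own decision
# values would be overconfident (the SVM separates its training data far
# better than unseen trials) and would bias the recognition rows away
# from the true conditional probabilities.
svm_fold_posteriors <- function(x_train, y_train, x_test, sigma, box,
                                cal_folds = 3, cal_seed = 1L) {
  dv_test <- svm_decision_values(x_train, y_train, x_test, sigma, box)
  cal_fold <- stratified_folds(y_train, cal_folds, cal_seed)
  dv_cal <- numeric(length(y_train))
  for (k in seq_len(cal_folds)) {
    inner <- cal_fold != k
    if (length(unique(y_train[inner])) < 2) next
    dv_cal[!inner] <- svm_decision_values(
      x_train[inner, , drop = FALSE], y_train[inner],
      x_train[!inner, , drop = FALSE], sigma, box)
  }
  co <- if (stats::sd(dv_cal) > 0) {
    cal <- suppressWarnings(
      stats::glm((y_train == 1L) ~ dv_cal, family = stats::binomial())
    )
    stats::coef(cal)
  } else {
    c(NA_real_, NA_real_)
  }
  if (anyNA(co)) {
    # degenerate decision values: fall back to the base-rate posterior
    co <- c(stats::qlogis(pmin(pmax(mean(y_train == 1L), 1e-6), 1 - 1e-6)), 0)
  }
  p1 <- stats::plogis(co[1] + co[2] * dv_test)
  p1 <- pmin(pmax(p1, 1e-9), 1 - 1e-9)
  cbind(p1, 1 - p1)
}

#' Tune SVM hyperparameters by cross-validated search
#'
#' Minimizes stratified 10-fold cross-validation misclassification over
#' log-uniform random draws of the kernel scale (`sigma`) and penalty bound
#' (`box`), both on `[1e-3, 1e5]`. Reproducible under `rng_seed`.
#'
#' @param features Feature tibble or matrix.
#' @param labels True category labels (1/2) per trial.
#' @param rng_seed Integer seed.
#' @param budget Number of candidate pairs (a warning is issued below 5).
#' @param folds Number of CV folds.
#' @return List with `sigma`, `box`, `cv_error`.
#' @export
tune_svm <- function(features, labels, rng_seed = 1L, budget = 30,
                     folds = 10) {
  x <- if (is.data.frame(features)) feature_matrix(features) else
    as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels[!is.na(labels)])) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  if (budget < 5) warning("tuning budget < 5; results may be poor")
  cand <- with_seed_(derive_seed(rng_seed, 1L), {
    cbind(sigma = 10^stats::runif(budget, -3, 5),
          box = 10^stats::runif(budget, -3, 5))
  })
  fold <- stratified_folds(labels, folds, derive_seed(rng_seed, 2L))
  err <- vapply(seq_len(budget), function(i) {
    wrong <- 0L
    for (k in seq_len(folds)) {
      tr <- fold != k
      if (length(unique(labels[tr])) < 2) next
      dv <- svm_decision_values(x[tr, , drop = FALSE], labels[tr],
                                x[!tr, , drop = FALSE],
                                cand[i, "sigma"], cand[i, "box"])
      pred <- ifelse(dv >= 0, 1L, 2L)
      wrong <- wrong + sum(pred != labels[!tr])
    }
    wrong / length(labels)
  }, numeric(1))
  best <- which.min(err)
  list(sigma = cand[best, "sigma"], box = cand[best, "box"],
       cv_error = err[best])
}

#' Cross-validated SVM posterior probabilities
#'
#' Trains an RBF-kernel SVM per stratified fold on the remaining folds and
#' returns, for every trial, the held-out posterior probability pair for
#' the two true categories, via a sigmoid (Platt-style) link calibrated on
#' the training-fold decision values. Every trial receives exactly one test
#' posterior; posteriors sum to 1 per trial. If a class is missing from a
#' training fold the partition is redrawn with a new derived seed.
#'
#' @param features Feature tibble or matrix.
#' @param labels True category labels (1/2).
#' @param sigma,box Hyperparameters (kernel scale, penalty bound).
#' @param folds Number of folds (each class needs at least `folds` trials).
#' @param rng_seed Integer seed controlling the partition.
#' @return Tibble with `p_nu1`, `p_nu2`, `predicted` per trial (input
#'   order).
#' @export
svm_cv_posteriors <- function(features, labels, sigma, box, folds = 10,
                              rng_seed = 1L) {
  x <- if (is.data.frame(features)) feature_matrix(features) else
    as.matrix(features)
  labels <- as.integer(labels)
  if (min(table(labels)) < folds) {
    stop("need at least `folds` trials per class", call. = FALSE)
  }
  for (attempt in 1:10) {
    fold <- stratified_folds(labels, folds, derive_seed(rng_seed, attempt))
    ok <- all(vapply(seq_len(folds), function(k) {
      length(unique(labels[fold != k])) == 2L
    }, logical(1)))
    if (ok) break
  }
  post <- matrix(NA_real_, length(labels), 2)
  for (k in seq_len(folds)) {
    tr <- fold != k
    post[!tr, ] <- svm_fold_posteriors(
      x[tr, , drop = FALSE], labels[tr], x[!tr, , drop = FALSE],
      sigma, box, cal_seed = derive_seed(rng_seed, 100L + k))
  }
  tibble::tibble(
    p_nu1 = post[, 1], p_nu2 = post[, 2],
    predicted = ifelse(post[, 1] >= 0.5, 1L, 2L)
  )
}

#' Recognition distribution from one classification repeat
#'
#' Averages the per-trial posterior pairs within each perception group:
#' `Q(nu | mu)` is the mean posterior for `nu` over trials whose perception
#' index is `mu`. Rows sum to 1 by construction.
#'
#' @param posteriors Tibble from [svm_cv_posteriors()].
#' @param per_trial_mu Perception index (1/2) per trial.
#' @return 2x2 matrix `Q`, rows indexed by perception state.
#' @export
estimate_recognition <- function(posteriors, per_trial_mu) {
  stopifnot(nrow(posteriors) == length(per_trial_mu))
  q <- matrix(NA_real_, 2, 2,
              dimnames = list(mu = c("mu1", "mu2"), nu = c("nu1", "nu2")))
  for (m in 1:2) {
    idx <- which(per_trial_mu == m)
    if (length(idx) == 0) {
      stop(sprintf("perception group %d is empty", m), call. = FALSE)
    }
    q[m, ] <- c(mean(posteriors$p_nu1[idx]), mean(posteriors$p_nu2[idx]))
  }
  q
}

#' Repeat K-means/SVM classification and average the estimates
#'
#' Runs `n_repeats` independent classification repeats, each with a fresh
#' K-means initialization and a fresh stratified CV partition, and averages
#' the per-repeat recognition distributions. Per-trial perception indices
#' and predicted labels are majority votes across repeats. Repeats whose
#' perception grouping degenerates (an empty group) are discarded; more
#' than 10% discarded aborts with an error.
#'
#' @param features Feature tibble from [extract_features()].
#' @param trials Trial table with `true_category` and `decision`.
#' @param sigma,box SVM hyperparameters (tune once via [tune_svm()]).
#' @param n_repeats Number of repeats (study default 200).
#' @param folds CV folds.
#' @param rng_seed Integer master seed; all repeat seeds derive from it.
#' @return Object of class `recognition_estimate`: `Q`, `per_trial_mu`,
#'   `per_trial_predicted_nu`, `kmeans_agreement`, `svm_cv_accuracy`,
#'   `hyperparams`, `n_repeats`, `n_discarded`.
#' @export
repeat_and_average <- function(features, trials, sigma, box,
                               n_repeats = 200, folds = 10, rng_seed = 1L) {
  if (n_repeats < 1) stop("`n_repeats` must be >= 1", call. = FALSE)
  labels <- as.integer(trials$true_category)
  n <- nrow(features)
  q_sum <- matrix(0, 2, 2)
  mu_votes <- matrix(0L, n, 2)
  pred_votes <- matrix(0L, n, 2)
  agree <- numeric(0)
  acc <- numeric(0)
  discarded <- 0L
  for (r in seq_len(n_repeats)) {
    seed_r <- derive_seed(rng_seed, r)
    cl <- cluster_perceptions(features, derive_seed(seed_r, 1L))
    mp <- map_clusters_to_perceptions(cl, trials$decision)
    post <- svm_cv_posteriors(features, labels, sigma, box, folds,
                              derive_seed(seed_r, 2L))
    q_r <- tryCatch(estimate_recognition(post, mp$mu), error = function(e) NULL)
    if (is.null(q_r)) {
      discarded <- discarded + 1L
      next
    }
    q_sum <- q_sum + q_r
    mu_votes[cbind(seq_len(n), mp$mu)] <- mu_votes[cbind(seq_len(n), mp$mu)] + 1L
    pred_votes[cbind(seq_len(n), post$predicted)] <-
      pred_votes[cbind(seq_len(n), post$predicted)] + 1L
    agree <- c(agree, mp$agreement)
    acc <- c(acc, mean(post$predicted == labels))
  }
  n_ok <- n_repeats - discarded
  if (discarded > 0.1 * n_repeats || n_ok == 0) {
    stop(sprintf("%d of %d repeats discarded (> 10%%)", discarded, n_repeats),
         call. = FALSE)
  }
  structure(
    list(
      Q = q_sum / n_ok,
      per_trial_mu = ifelse(mu_votes[, 1] >= mu_votes[, 2], 1L, 2L),
      per_trial_predicted_nu = ifelse(pred_votes[, 1] >= pred_votes[, 2],
                                      1L, 2L),
      kmeans_agreement = mean(agree),
      svm_cv_accuracy = mean(acc),
      hyperparams = c(sigma = sigma, box = box),
      n_repeats = n_ok, n_discarded = discarded
    ),
    class = "recognition_estimate"
  )
}

#' @export
print.recognition_estimate <- function(x, ...) {
  cat(sprintf(
    "<recognition_estimate> %d repeats; K-means agreement %.3f; SVM CV accuracy %.3f\n",
    x$n_repeats, x$kmeans_agreement, x$svm_cv_accuracy))
  print(round(x$Q, 3))
  invisible(x)
}
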