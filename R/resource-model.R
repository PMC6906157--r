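# Bounded-rationality resource parameter (softmax inverse temperature)
# estimated from categorization behavior.

#' Empirical decision probabilities
#'
#' From the responded trials, computes the decision-given-category
#' confusion matrix `P(d_i | nu_j, m)` and the marginal decision
#' probabilities `P(d_i | m) = sum_j P(d_i | nu_j, m) P(nu_j | m)` with the
#' balanced task prior `P(nu_j | m) = 0.5`.
#'
#' @param trials Trial table with `true_category` and `decision` (NA =
#'   non-response, excluded).
#' @return List with `confusion` (2x2, rows decision, columns category;
#'   columns sum to 1), `P_d` (length 2) and `degenerate` (TRUE if some
#'   decision was never made).
#' @export
decision_probabilities <- function(trials) {
  resp <- trials[!is.na(trials$decision), ]
  if (nrow(resp) == 0 || length(unique(resp$true_category)) < 2) {
    stop("need responded trials for both true categories", call. = FALSE)
  }
  confusion <- matrix(0, 2, 2, dimnames = list(d = c("d1", "d2"),
                                               nu = c("nu1", "nu2")))
  for (j in 1:2) {
    nj <- resp[resp$true_category == j, ]
    confusion[, j] <- c(mean(nj$decision == 1), mean(nj$decision == 2))
  }
  P_d <- as.numeric(confusion %*% c(0.5, 0.5))
  list(confusion = confusion, P_d = P_d, degenerate = any(P_d == 0))
}

#' Decision utilities
#'
#' `U(d_i | m) = ln P(d_i | m)`. The per-trial utility vector is non-zero
#' only for the decision actually made on that trial (the other decision's
#' utility is zeroed), reflecting that a decision is valued through the
#' perceived category actually chosen.
#'
#' @param P_d Length-2 marginal decision probabilities, entries in (0, 1).
#' @return Length-2 utilities in nats.
#' @export
decision_utilities <- function(P_d) {
  if (any(P_d <= 0) || any(P_d >= 1)) {
    stop("degenerate decision probabilities; collect more trials",
         call. = FALSE)
  }
  log(P_d)
}

#' Softmax decision probability
#'
#' Under equal priors the softmax reduces to a logistic in the utility
#' difference: `P(d1) = 1 / (1 + exp(-zeta (U1 - U2)))`.
#'
#' @param U1,U2 Decision utilities.
#' @param zeta Resource (inverse temperature) parameter.
#' @return `P(d1)`.
#' @export
softmax_probability <- function(U1, U2, zeta) {
  stats::plogis(zeta * (U1 - U2))
}

#' Fit the resource parameter from categorization behavior
#'
#' Builds the per-trial utility regressor
#' `x_t = U(d1|m) 1[d_t = 1] - U(d2|m) 1[d_t = 2]` (the unchosen decision's
#' utility is zeroed) and fits an intercept-free logistic regression of the
#' true-category indicator `y_t = 1[nu_t = 1]` on `x_t`; the coefficient is
#' the resource parameter `zeta`. A regression of the decision itself on
#' this regressor would be perfectly separable (the regressor's sign is a
#' function of the decision), so the category-side response is the one that
#' yields finite estimates -- and it reproduces the group parameter values
#' implied by the group accuracies. Under balanced decisions the estimate
#' admits the closed form `-logit(p_correct)/ln 2`.
#'
#' @param trials Trial table with `true_category` and `decision`.
#' @return Object of class `softmax_fit`: `zeta`, `standard_error`, `U_d`,
#'   `P_d`, `confusion`, `n_trials`, `accuracy`, `method`.
#' @export
fit_zeta <- function(trials) {
  resp <- trials[!is.na(trials$decision), ]
  if (nrow(resp) < 20) {
    stop("need at least 20 responded trials", call. = FALSE)
  }
  if (length(unique(resp$decision)) < 2) {
    stop("both decisions must be present", call. = FALSE)
  }
  acc <- mean(resp$decision == resp$true_category)
  if (acc == 1) {
    stop(paste("perfect accuracy: the resource parameter diverges;",
               "the participant behaves as an unbounded categorizer"),
         call. = FALSE)
  }
  dp <- decision_probabilities(resp)
  U <- decision_utilities(dp$P_d)
  x <- ifelse(resp$decision == 1L, U[1], -U[2])
  y <- as.integer(resp$true_category == 1L)
  fit <- suppressWarnings(
    stats::glm(y ~ 0 + x, family = stats::binomial())
  )
  structure(
    list(zeta = unname(stats::coef(fit)["x"]),
         standard_error = unname(sqrt(stats::vcov(fit)[1, 1])),
         U_d = U, P_d = dp$P_d, confusion = dp$confusion,
         n_trials = nrow(resp), accuracy = acc,
         method = "intercept-free logistic regression of 1[nu=1] on the per-trial utility regressor"),
    class = "softmax_fit"
  )
}

#' @export
print.softmax_fit <- function(x, ...) {
  cat(sprintf(
    "<softmax_fit> zeta = %.4f (SE %.4f), accuracy %.3f over %d trials\n",
    x$zeta, x$standard_error, x$accuracy, x$n_trials))
  invisible(x)
}

#' Closed-form resource parameter under balanced decisions
#'
#' With balanced decisions (`P_d = c(0.5, 0.5)`) the utility regressor is
#' `-+ln 2` and the logistic fit reduces to `zeta = -logit(p)/ln 2`, where
#' `p` is the proportion correct. Used as the analytic oracle for
#' [fit_zeta()].
#'
#' @param p Proportion correct, in (0, 1).
#' @return The resource parameter.
#' @export
zeta_closed_form <- function(p) {
  assert_prob(p, "p")
  -stats::qlogis(p) / log(2)
}

#' Construct a balanced trial table at a fixed accuracy
#'
#' Builds a deterministic trial table with `n/2` trials per true category,
#' equal decision frequencies, and proportion correct as close to `accuracy`
#' as the trial count allows. Used to reconstruct group-level resource
#' parameters from printed group accuracies.
#'
#' @param n Total trials (multiple of 2; accuracy is realized exactly when
#'   `n/2 * accuracy` is an integer).
#' @param accuracy Target proportion correct.
#' @return Trial table tibble with `trial`, `true_category`, `decision`.
#' @export
balanced_trials <- function(n, accuracy) {
  assert_prob(accuracy, "accuracy")
  if (n %% 2 != 0) stop("`n` must be even", call. = FALSE)
  half <- n / 2
  n_corr <- round(half * accuracy)
  nu <- rep(c(1L, 2L), each = half)
  d <- c(rep(1L, n_corr), rep(2L, half - n_corr),
         rep(2L, n_corr), rep(1L, half - n_corr))
  tibble::tibble(trial = seq_len(n), true_category = nu, decision = d)
}
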