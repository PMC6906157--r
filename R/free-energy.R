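# Free-energy differences between the recognition distribution and the
# optimal generative model, and the Boltzmann utility/information trade-off.

#' Build the optimal generative model distribution
#'
#' The ideal noise-free categorizer maps each optimal category perception
#' one-to-one onto its true category label, so the joint distribution
#' `P(o, nu | M)` is diagonal with entries `prior` (0.5 for the balanced
#' task). Exact off-diagonal zeros would make the free-energy difference
#' infinite, so they are replaced by a small configurable `epsilon`
#' (default 1e-3, which places the per-state differences in the 2--4 nat
#' range and the four-state total near 12.6 nats when the recognition rows
#' track typical classifier accuracies). `epsilon` is reported in all
#' outputs.
#'
#' @param prior Category prior (0.5 in the balanced task).
#' @param epsilon Off-diagonal regularization, `0 < epsilon < prior`.
#' @return Object of class `generative_model` with the 2x2 matrix `P`
#'   (rows: optimal perception `o`; columns: true category `nu`).
#' @export
#' @examples
#' build_generative_model()
build_generative_model <- function(prior = 0.5, epsilon = 1e-3) {
  if (!(epsilon > 0 && epsilon < prior)) {
    stop("`epsilon` must satisfy 0 < epsilon < prior", call. = FALSE)
  }
  P <- matrix(c(prior, epsilon, epsilon, prior), 2, 2,
              dimnames = list(o = c("o1", "o2"), nu = c("nu1", "nu2")))
  structure(list(P = P, prior = prior, epsilon = epsilon),
            class = "generative_model")
}

#' Free-energy difference for one (o, mu) state
#'
#' `deltaF = sum_nu q(nu) ln q(nu) - sum_nu q(nu) ln P(o, nu | M)` in nats,
#' where `q` is the recognition row `Q(. | mu)`. Entries of `q` equal to 0
#' contribute 0 to the entropy term (the continuity convention
#' `0 ln 0 = 0`); the cross term uses the epsilon-regularized generative
#' model, so it stays finite.
#'
#' @param q_row Length-2 recognition distribution (must sum to 1).
#' @param o Optimal category perception (1 or 2).
#' @param gm A [build_generative_model()].
#' @return Free-energy difference in nats.
#' @export
delta_F <- function(q_row, o, gm) {
  stopifnot(inherits(gm, "generative_model"), o %in% c(1, 2))
  if (length(q_row) != 2 || any(q_row < 0) ||
      abs(sum(q_row) - 1) > 1e-6) {
    stop("`q_row` must be a length-2 distribution summing to 1",
         call. = FALSE)
  }
  ent <- sum(ifelse(q_row > 0, q_row * log(q_row), 0))
  cross <- sum(q_row * log(gm$P[o, ]))
  ent - cross
}

#' Free-energy differences for all four (o, mu) states
#'
#' @param Q 2x2 recognition matrix (rows `mu`, columns `nu`, rows sum
#'   to 1), e.g. from [repeat_and_average()].
#' @param gm A [build_generative_model()].
#' @return Object of class `free_energy_result`: `dF` (2x2, rows `o`,
#'   columns `mu`), `dF_total`, `matched_mean`, `mismatched_mean`,
#'   `epsilon_used`.
#' @export
free_energy <- function(Q, gm = build_generative_model()) {
  Q <- if (inherits(Q, "recognition_estimate")) Q$Q else Q
  dF <- matrix(0, 2, 2, dimnames = list(o = c("o1", "o2"),
                                        mu = c("mu1", "mu2")))
  for (o in 1:2) {
    for (m in 1:2) dF[o, m] <- delta_F(Q[m, ], o, gm)
  }
  cm <- collapse_match_mismatch(dF)
  structure(
    list(dF = dF, dF_total = total_delta_F(dF),
         matched_mean = cm[["matched_mean"]],
         mismatched_mean = cm[["mismatched_mean"]],
         epsilon_used = gm$epsilon),
    class = "free_energy_result"
  )
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat("<free_energy_result> (nats)\n")
  print(round(x$dF, 3))
  cat(sprintf("total %.3f; matched %.3f; mismatched %.3f (epsilon %g)\n",
              x$dF_total, x$matched_mean, x$mismatched_mean,
              x$epsilon_used))
  invisible(x)
}

#' Total free-energy difference
#'
#' Sum of the four per-state differences.
#'
#' @param dF 2x2 matrix of finite free-energy differences.
#' @return Total in nats.
#' @export
total_delta_F <- function(dF) {
  stopifnot(is.matrix(dF), all(dim(dF) == 2), all(is.finite(dF)))
  sum(dF)
}

#' Collapse the four states to matched/mismatched means
#'
#' Matched: the diagonal states where the brain's perception encoding
#' agrees with the optimal perception; mismatched: the off-diagonal states.
#'
#' @param dF 2x2 matrix (rows `o`, columns `mu`).
#' @return Named numeric vector `matched_mean`, `mismatched_mean`.
#' @export
collapse_match_mismatch <- function(dF) {
  stopifnot(is.matrix(dF), all(dim(dF) == 2), all(is.finite(dF)))
  c(matched_mean = mean(c(dF[1, 1], dF[2, 2])),
    mismatched_mean = mean(c(dF[1, 2], dF[2, 1])))
}

#' Negative free-energy difference of a bounded-rational decision
#'
#' Computes `-deltaF = sum_nu q(nu) U(nu) - (1/zeta) sum_nu q(nu)
#' ln(q(nu)/p0(nu))`: expected utility minus the information-processing
#' cost of moving from the prior `p0` to the final distribution `q`,
#' priced at the inverse of the resource parameter `zeta`. As allocated
#' resources `zeta` grow, the magnitude of the free-energy difference
#' shrinks.
#'
#' @param q Final distribution over outcomes.
#' @param p0 Prior distribution (must dominate `q`: `q > 0` only where
#'   `p0 > 0`).
#' @param U Utilities per outcome.
#' @param zeta Resource parameter (nonzero).
#' @return Negative free-energy difference (utility units).
#' @export
boltzmann_negative_delta_F <- function(q, p0, U, zeta) {
  if (zeta == 0) stop("`zeta` must be nonzero", call. = FALSE)
  stopifnot(length(q) == length(p0), length(q) == length(U))
  if (any(q > 0 & p0 == 0)) {
    stop("`q` must be absolutely continuous w.r.t. `p0`", call. = FALSE)
  }
  kl <- sum(ifelse(q > 0, q * log(q / p0), 0))
  sum(q * U) - kl / zeta
}

#' Negative free-energy difference over a resource-parameter grid
#'
#' Evaluates [boltzmann_negative_delta_F()] over a grid of `zeta` values,
#' tracing the reciprocal relationship between allocated resources and the
#' free-energy difference magnitude.
#'
#' @param zeta_grid Numeric vector of nonzero `zeta` values.
#' @inheritParams boltzmann_negative_delta_F
#' @return Tibble with `zeta` and `neg_delta_F`.
#' @export
boltzmann_curve <- function(zeta_grid, q, p0, U) {
  tibble::tibble(
    zeta = zeta_grid,
    neg_delta_F = vapply(zeta_grid, function(z)
      boltzmann_negative_delta_F(q, p0, U, z), numeric(1))
  )
}
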