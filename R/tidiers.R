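# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method
tidy.softmax_fit <- function(x, ...) {
  tibble::tibble(term = "zeta", estimate = x$zeta,
                 std.error = x$standard_error)
}

#' @exportS3Method
glance.softmax_fit <- function(x, ...) {
  tibble::tibble(zeta = x$zeta, accuracy = x$accuracy,
                 n_trials = x$n_trials,
                 U_d1 = x$U_d[1], U_d2 = x$U_d[2])
}

#' @exportS3Method
tidy.free_energy_result <- function(x, ...) {
  tibble::tibble(
    o = rep(1:2, times = 2), mu = rep(1:2, each = 2),
    state = ifelse(rep(1:2, times = 2) == rep(1:2, each = 2),
                   "matched", "mismatched"),
    delta_F = as.vector(x$dF)
  )
}

#' @exportS3Method
glance.free_energy_result <- function(x, ...) {
  tibble::tibble(dF_total = x$dF_total, matched_mean = x$matched_mean,
                 mismatched_mean = x$mismatched_mean,
                 epsilon = x$epsilon_used)
}

#' @exportS3Method
tidy.recognition_estimate <- function(x, ...) {
  tibble::tibble(
    mu = rep(1:2, times = 2), nu = rep(1:2, each = 2),
    q = as.vector(x$Q)
  )
}

#' @exportS3Method
glance.recognition_estimate <- function(x, ...) {
  tibble::tibble(kmeans_agreement = x$kmeans_agreement,
                 svm_cv_accuracy = x$svm_cv_accuracy,
                 sigma = x$hyperparams[["sigma"]],
                 box = x$hyperparams[["box"]],
                 n_repeats = x$n_repeats)
}

#' @exportS3Method
tidy.perm_anova <- function(x, ...) x$result

#' @exportS3Method
tidy.randomization_corr <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p_value, n = x$n)
}

#' @exportS3Method
tidy.maxstat_test <- function(x, ...) x$result

#' @exportS3Method
tidy.cohort_report <- function(x, ...) x$participants

#' @exportS3Method
glance.cohort_report <- function(x, ...) {
  tibble::tibble(
    n_participants = nrow(x$participants),
    task = x$config$task,
    mean_accuracy = mean(x$participants$accuracy),
    mean_zeta = mean(x$participants$zeta),
    mean_dF_total = mean(x$participants$dF_total),
    r_dF_zeta = x$correlations$r[x$correlations$contrast ==
                                   "dF_total_vs_zeta"]
  )
}
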