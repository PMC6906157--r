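# Per-participant and cohort orchestration.

#' Run the full analysis for one participant
#'
#' Sequences the whole per-participant pipeline: preprocessing (artifact
#' scoring, average reference, band-pass, baseline), PCA whitening, CSP
#' fitting on the behaviorally indexed perception classes, one
#' hyperparameter tuning pass, `repeats` K-means/SVM classification repeats
#' averaged into the recognition distribution, free-energy differences
#' against the epsilon-regularized optimal generative model, the behavioral
#' resource-parameter fit, and matched/mismatched ERP-GFP waveforms. Fully
#' deterministic given `rng_seed`.
#'
#' @param epochs An [epoch_set()] with a trial table attached (needs
#'   `true_category`, `decision`).
#' @param repeats Number of classification repeats (study default 200).
#' @param epsilon Generative-model regularization.
#' @param tune_budget Hyperparameter search budget.
#' @param folds CV folds.
#' @param artifact_threshold Peak-to-peak artifact criterion, microvolts.
#' @param rng_seed Integer master seed for this participant.
#' @return Object of class `participant_result`.
#' @export
run_participant <- function(epochs, repeats = 200, epsilon = 1e-3,
                            tune_budget = 30, folds = 10,
                            artifact_threshold = 150, rng_seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"), !is.null(epochs$trials))
  clean <- preprocess(epochs, artifact_threshold = artifact_threshold)
  trials <- clean$trials
  analysis <- !is.na(trials$decision)
  if (sum(analysis) < 20) {
    stop(sprintf(
      "stage preprocess: only %d artifact-free responded trials (< 20)",
      sum(analysis)), call. = FALSE)
  }
  clean <- subset_trials(clean, analysis)
  trials <- clean$trials

  wh <- reduce_whiten(clean)
  comp <- apply_transform(clean, wh)
  csp <- fit_csp(comp, trials$decision)
  features <- extract_features(comp, csp)

  tuned <- tune_svm(features, trials$true_category,
                    rng_seed = derive_seed(rng_seed, 1L),
                    budget = tune_budget, folds = folds)
  recog <- repeat_and_average(features, trials, sigma = tuned$sigma,
                              box = tuned$box, n_repeats = repeats,
                              folds = folds,
                              rng_seed = derive_seed(rng_seed, 2L))
  gm <- build_generative_model(epsilon = epsilon)
  fe <- free_energy(recog, gm)
  sf <- fit_zeta(trials)

  match_state <- ifelse(recog$per_trial_mu == trials$true_category,
                        "matched", "mismatched")
  gfp <- if (length(unique(match_state)) == 2) {
    erp_gfp(clean, match_state)
  }

  structure(
    list(
      behavior = {
        corr <- trials$decision == trials$true_category
        rt <- trials$rt_ms %||% rep(NA_real_, nrow(trials))
        tibble::tibble(
          accuracy = mean(corr),
          rt_correct = stats::median(rt[corr], na.rm = TRUE),
          rt_incorrect = stats::median(rt[!corr], na.rm = TRUE),
          n_trials = nrow(trials)
        )
      },
      recognition = recog, free_energy = fe, softmax = sf, gfp = gfp,
      whitener_rank = wh$rank, seed = rng_seed
    ),
    class = "participant_result"
  )
}

#' @export
print.participant_result <- function(x, ...) {
  cat(sprintf(
    "<participant_result> accuracy %.3f; zeta %.3f; dF_total %.3f nats (matched %.3f < mismatched %.3f: %s)\n",
    x$behavior$accuracy, x$softmax$zeta, x$free_energy$dF_total,
    x$free_energy$matched_mean, x$free_energy$mismatched_mean,
    x$free_energy$matched_mean < x$free_energy$mismatched_mean))
  invisible(x)
}

#' Run a synthetic cohort analysis
#'
#' Generates and analyzes `cfg$n_participants` synthetic participants one
#' at a time (participant seeds derive from the master seed), then computes
#' the cohort statistics: the randomization correlation between the total
#' free-energy difference and the fitted resource parameter, and the
#' workload correlations with both, with BH-FDR correction over the
#' correlation family.
#'
#' @param cfg A [cohort_config()].
#' @param repeats Classification repeats per participant.
#' @param tune_budget Hyperparameter search budget per participant.
#' @param epsilon Generative-model regularization.
#' @param n_rand Randomizations for the correlation tests.
#' @param progress Print one line per participant.
#' @return Object of class `cohort_report`: `participants` tibble,
#'   `correlations` tibble (with FDR-corrected significance), `config`.
#' @export
run_cohort <- function(cfg, repeats = 200, tune_budget = 30,
                       epsilon = 1e-3, n_rand = 5000, progress = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_participants < 6) stop("need >= 6 participants", call. = FALSE)
  rows <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    sim <- simulate_participant(cfg, i)
    res <- run_participant(sim$epochs, repeats = repeats,
                           epsilon = epsilon, tune_budget = tune_budget,
                           rng_seed = derive_seed(cfg$master_seed, 2000L + i))
    rows[[i]] <- tibble::tibble(
      participant = i, task = cfg$task, p_true = sim$p,
      zeta_true = sim$zeta_true, workload = sim$workload,
      accuracy = res$behavior$accuracy, zeta = res$softmax$zeta,
      dF_11 = res$free_energy$dF[1, 1], dF_12 = res$free_energy$dF[1, 2],
      dF_21 = res$free_energy$dF[2, 1], dF_22 = res$free_energy$dF[2, 2],
      dF_total = res$free_energy$dF_total,
      matched_mean = res$free_energy$matched_mean,
      mismatched_mean = res$free_energy$mismatched_mean,
      svm_cv_accuracy = res$recognition$svm_cv_accuracy,
      kmeans_agreement = res$recognition$kmeans_agreement
    )
    if (progress) {
      message(sprintf("participant %d/%d: acc %.2f zeta %.2f dF %.2f",
                      i, cfg$n_participants, rows[[i]]$accuracy,
                      rows[[i]]$zeta, rows[[i]]$dF_total))
    }
  }
  participants <- dplyr::bind_rows(rows)
  seed0 <- derive_seed(cfg$master_seed, 9000L)
  tests <- list(
    dF_total_vs_zeta = randomization_corr(participants$dF_total,
                                          participants$zeta, n_rand,
                                          derive_seed(seed0, 1L)),
    workload_vs_zeta = randomization_corr(participants$workload,
                                          participants$zeta, n_rand,
                                          derive_seed(seed0, 2L)),
    workload_vs_dF_total = randomization_corr(participants$workload,
                                              participants$dF_total, n_rand,
                                              derive_seed(seed0, 3L))
  )
  correlations <- tibble::tibble(
    contrast = names(tests),
    r = vapply(tests, function(t) t$r, numeric(1)),
    p_value = vapply(tests, function(t) t$p_value, numeric(1))
  )
  correlations$significant_fdr <-
    seq_len(nrow(correlations)) %in% fdr_bh(correlations$p_value, 0.05)
  structure(list(participants = participants, correlations = correlations,
                 config = cfg),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d participants, task %s\n",
              nrow(x$participants), x$config$task))
  cat(sprintf("  mean accuracy %.3f; mean zeta %.3f; mean dF_total %.3f\n",
              mean(x$participants$accuracy), mean(x$participants$zeta),
              mean(x$participants$dF_total)))
  print(as.data.frame(x$correlations))
  invisible(x)
}

#' Compare two task conditions across a cohort
#'
#' Permutation one-way repeated-measures ANOVA of a per-participant
#' measure between two cohort reports (e.g. the II and RB variants run on
#' the same participant indices).
#'
#' @param report_a,report_b Two [run_cohort()] reports with the same
#'   participant count.
#' @param measure Column of the participants table to compare.
#' @param n_perm Permutations.
#' @param rng_seed Integer seed.
#' @return A [perm_rm_anova()] result.
#' @export
compare_tasks <- function(report_a, report_b, measure = "dF_total",
                          n_perm = 5000, rng_seed = 1L) {
  a <- report_a$participants[[measure]]
  b <- report_b$participants[[measure]]
  stopifnot(length(a) == length(b))
  perm_rm_anova(cbind(a, b), factor(c("task_a", "task_b")), n_perm,
                rng_seed)
}
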