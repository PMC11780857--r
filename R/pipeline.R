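#' Default end-to-end run configuration
#'
#' All randomness in a run flows from the single `seed`; stage seeds are
#' derived from it so stages are independently reproducible. The mixture
#' stage defaults to the 5000-repetition permutation estimator; set
#' `mixture_method = "exact"` for the deterministic pool enumeration.
#'
#' @param seed Root seed.
#' @param n_per_group Participants per clinical group.
#' @param sessions 1 or 2.
#' @param n_reps Permutation repetitions per trial.
#' @param mixture_method `"permutation"` or `"exact"`.
#' @param cv_folds Cross-validation folds for the classifiers.
#' @param svm_cost SVM regularization parameter.
#' @return A named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, n_per_group = 20L, sessions = 1L,
                           n_reps = 5000L, mixture_method = "permutation",
                           cv_folds = 5L, svm_cost = 1) {
  list(seed = as.integer(seed), n_per_group = n_per_group,
       sessions = as.integer(sessions), n_reps = as.integer(n_reps),
       mixture_method = mixture_method, cv_folds = as.integer(cv_folds),
       svm_cost = svm_cost)
}

OMT_METRICS <- c("identification_accuracy", "abs_localization_error",
                 "identification_time_s", "localization_time_s",
                 "target_detection", "misbinding", "guessing", "imprecision")

#' Run the full simulate-score-analyse pipeline
#'
#' Simulates a cohort, computes per-participant basic and mixture metrics,
#' runs the covariate-adjusted cross-sectional group comparisons, the
#' set-size-by-delay repeated-measures ANOVAs and the hippocampal-volume
#' regressions, adds the longitudinal analyses when two sessions were
#' simulated, and evaluates the overall and pairwise classifiers. When
#' `out_dir` is given, writes `participants.csv`, `trials.csv`,
#' `metrics.csv`, `stats_report.json` and `classification_report.json`
#' there, together with a `manifest.json` recording the full configuration.
#'
#' @param config List from [default_config()].
#' @param out_dir Optional output directory.
#' @return A list with elements `cohort`, `metrics` (participant-session
#'   table), `cross_sectional`, `factorial`, `hv`, `longitudinal` (or
#'   `NULL`), `classification`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  seeds <- derive_seeds(config$seed, c("cohort", "mixture", "cv"))
  cohort <- make_cohort(n_per_group = config$n_per_group,
                        sessions = config$sessions, seed = seeds[["cohort"]])
  set.seed(seeds[["mixture"]])
  scored <- score_cohort(cohort$trials, n_reps = config$n_reps,
                         method = config$mixture_method)
  metrics <- merge(cohort$participants, scored,
                   by = c("participant_id", "session"))
  metrics$gender_num <- as.numeric(metrics$gender == "F")
  baseline <- metrics[metrics$session == 1L, , drop = FALSE]

  cross_sectional <- lapply(stats::setNames(OMT_METRICS, OMT_METRICS),
                            function(m) ancova_groups(baseline, m))
  factorial <- list(
    identification_accuracy = factorial_2x2(
      condition_long(baseline, "ia_"), factors = "both"),
    abs_localization_error = factorial_2x2(
      condition_long(baseline, "ale_"), factors = "both"),
    target_detection = factorial_2x2(
      condition_long(baseline, "td_"), factors = "both"),
    guessing = factorial_2x2(condition_long(baseline, "gs_"),
                             factors = "both"),
    imprecision = factorial_2x2(condition_long(baseline, "impr_"),
                                factors = "both"),
    misbinding = factorial_2x2(condition_long(baseline, "mb_"),
                               factors = "delay")
  )
  hv <- lapply(stats::setNames(OMT_METRICS, OMT_METRICS),
               function(m) glm_hv(baseline, m))

  longitudinal <- NULL
  if (config$sessions >= 2L) {
    eff <- lapply(stats::setNames(OMT_METRICS, OMT_METRICS),
                  function(m) longitudinal_ancova(metrics, m))
    s1 <- metrics[metrics$session == 1L, ]
    s2 <- metrics[metrics$session == 2L, ]
    s2 <- s2[match(s1$participant_id, s2$participant_id), ]
    decline <- lapply(stats::setNames(OMT_METRICS, OMT_METRICS), function(m) {
      predict_decline(s1[[m]], s1$ace, s2$ace, predictor_name = m)
    })
    longitudinal <- list(ancova = eff, decline = decline)
  }

  classification <- list(
    overall = fit_eval_classifier(baseline, feature_set_columns("omt"),
                                  folds = config$cv_folds,
                                  seed = seeds[["cv"]],
                                  cost = config$svm_cost),
    overall_ace = fit_eval_classifier(baseline, feature_set_columns("ace"),
                                      folds = config$cv_folds,
                                      seed = seeds[["cv"]],
                                      cost = config$svm_cost),
    pairwise = pairwise_suite(baseline, folds = config$cv_folds,
                              seed = seeds[["cv"]], cost = config$svm_cost)
  )

  result <- list(cohort = cohort, metrics = metrics,
                 cross_sectional = cross_sectional, factorial = factorial,
                 hv = hv, longitudinal = longitudinal,
                 classification = classification, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Stage seeds derived deterministically from the root seed, kept within
# 32-bit integer range.
derive_seeds <- function(seed, names) {
  set.seed(as.integer(seed))
  stats::setNames(sample.int(.Machine$integer.max, length(names)), names)
}

# Long per-condition table for the repeated-measures ANOVA, from wide
# per-condition metric columns with a given prefix.
condition_long <- function(metrics, prefix) {
  cols <- grep(paste0("^", prefix, "ss"), names(metrics), value = TRUE)
  pieces <- lapply(cols, function(cl) {
    m <- regmatches(cl, regexec("ss([13])_d([14])", cl))[[1]]
    data.frame(participant_id = metrics$participant_id,
               set_size = as.integer(m[2]), delay_s = as.numeric(m[3]),
               value = metrics[[cl]])
  })
  do.call(rbind, pieces)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(result$cohort, out_dir)
  utils::write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  stats_report <- list(
    cross_sectional = lapply(result$cross_sectional, unclass),
    factorial = result$factorial,
    hv = result$hv,
    longitudinal = result$longitudinal
  )
  jsonlite::write_json(stats_report, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  cls <- result$classification
  classification_report <- list(
    overall = list(auc = as.list(cls$overall$auc),
                   accuracy = cls$overall$accuracy),
    overall_ace = list(auc = as.list(cls$overall_ace$auc),
                       accuracy = cls$overall_ace$accuracy),
    pairwise = cls$pairwise
  )
  jsonlite::write_json(classification_report,
                       file.path(out_dir, "classification_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(result$config, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
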