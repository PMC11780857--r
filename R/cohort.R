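GROUP_LEVELS <- c("EHC", "SCD", "MCI", "AD")

#' Default latent-severity and covariate settings for cohort simulation
#'
#' A single standardized latent severity drives (i) within-group perturbation
#' of the generative mixture parameters, (ii) the ACE cognitive screen and
#' (iii) hippocampal volume, so that task metrics, ACE and HV are mutually
#' correlated as in a memory-clinic cohort. Group severity means increase
#' from healthy controls to dementia; age/education means differ by group
#' (SCD youngest) so that covariate adjustment is genuinely exercised.
#'
#' `ace_slope`/`hv_slope` are losses per unit severity; `severity_progress_*`
#' define the one-year severity increase `delta = intercept + slope * s`
#' that generates follow-up ACE (faster progression at higher baseline
#' severity, so baseline task performance predicts subsequent decline).
#'
#' @return A list of model constants; pass (possibly modified) to
#'   [make_cohort()].
#' @export
default_covariate_model <- function() {
  list(
    severity_mean = c(EHC = 0, SCD = 0.35, MCI = 1.3, AD = 2.3),
    severity_sd = 0.55,
    # a general-competence trait, uncorrelated with diagnosis, shifts all of
    # a participant's parameters jointly; it caps multi-metric separability
    trait_sd = 1.0,
    # loadings of centred severity (plus trait) on generative parameters
    load_logit_p_target = -0.35,
    load_logit_p_misbind = 0.25,
    load_log_sigma = 0.35,
    load_logit_p_identify = -0.40,
    jitter_logit_sd = 0.30,
    jitter_log_sigma_sd = 0.15,
    # ACE / hippocampal-volume link
    ace_baseline = 97, ace_slope = 10, ace_noise_sd = 2.5,
    hv_baseline = 8300, hv_slope = 900, hv_noise_sd = 350, hv_floor = 2000,
    # longitudinal severity progression (per year)
    severity_progress_intercept = 0.25,
    severity_progress_slope = 0.50,
    severity_progress_sd = 0.10,
    # demographics
    age_mean = c(EHC = 70, SCD = 65, MCI = 72, AD = 74),
    age_sd = 6,
    education_mean = c(EHC = 15, SCD = 15, MCI = 13, AD = 12),
    education_sd = 2.5,
    p_female = 0.5
  )
}

#' Map latent severity to ACE score and hippocampal volume
#'
#' Both outcomes decline linearly in severity with additive Gaussian noise;
#' ACE is clipped to its 0--100 range and hippocampal volume floored at a
#' positive minimum.
#'
#' @param severity Numeric vector of standardized severities.
#' @param model Constants from [default_covariate_model()].
#' @return Data frame with columns `ace` and `hv_mm3`.
#' @export
latent_severity_link <- function(severity, model = default_covariate_model()) {
  n <- length(severity)
  ace <- model$ace_baseline - model$ace_slope * severity +
    stats::rnorm(n, 0, model$ace_noise_sd)
  hv <- model$hv_baseline - model$hv_slope * severity +
    stats::rnorm(n, 0, model$hv_noise_sd)
  data.frame(
    ace = pmin(pmax(ace, 0), 100),
    hv_mm3 = pmax(hv, model$hv_floor)
  )
}

clamp01 <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)

# Perturb a group preset for one participant: centred-severity loadings plus
# independent jitter, on the logistic scale for probabilities and the log
# scale for sigma. The mixture weights are renormalized afterwards.
individual_params <- function(preset, centred_severity, model) {
  lp <- function(p, load, sd) {
    clamp01(stats::plogis(stats::qlogis(clamp01(p)) +
                            load * centred_severity + stats::rnorm(1, 0, sd)))
  }
  pt <- lp(preset$p_target, model$load_logit_p_target, model$jitter_logit_sd)
  pm <- lp(preset$p_misbind, model$load_logit_p_misbind, model$jitter_logit_sd)
  pg <- preset$p_guess # absorbs the renormalization
  tot <- pt + pm + pg
  sigma <- preset$sigma *
    exp(model$load_log_sigma * centred_severity +
          stats::rnorm(1, 0, model$jitter_log_sigma_sd))
  shift <- model$load_logit_p_identify * centred_severity +
    stats::rnorm(1, 0, model$jitter_logit_sd)
  pid <- clamp01(stats::plogis(stats::qlogis(clamp01(preset$p_identify)) + shift))
  generative_params(
    p_target = pt / tot, p_misbind = pm / tot, p_guess = pg / tot,
    sigma = sigma, p_identify = pid,
    rt_ident_mu = preset$rt_ident_mu + 0.05 * centred_severity,
    rt_ident_sigma = preset$rt_ident_sigma,
    rt_loc_mu = preset$rt_loc_mu + 0.05 * centred_severity,
    rt_loc_sigma = preset$rt_loc_sigma,
    session_drift = preset$session_drift
  )
}

#' Simulate a multi-group (optionally longitudinal) cohort
#'
#' Each participant receives an independent session schedule, individual
#' generative parameters perturbed around their group preset by a latent
#' severity, demographic covariates, and severity-linked ACE and hippocampal
#' volume. With `sessions = 2` every participant is re-tested on a fresh
#' schedule with the group's per-session parameter drift applied and
#' follow-up ACE generated from progressed severity.
#'
#' @param n_per_group Named integer vector of group sizes (names from
#'   `EHC, SCD, MCI, AD`), or a single number recycled to all four groups.
#' @param group_presets Named list of `omt_params`, as
#'   [default_group_presets()].
#' @param covariate_model Constants from [default_covariate_model()].
#' @param sessions 1 (cross-sectional) or 2 (adds a one-year follow-up).
#' @param seed Integer root seed; all schedules and responses derive from it.
#' @param schedule_args Extra arguments passed to [make_session_schedule()].
#' @return A list with two data frames: `participants` (one row per
#'   participant-session: `participant_id`, `group`, `session`, `age`,
#'   `gender`, `education`, `ace`, `hv_mm3`, `severity`, plus true generative
#'   parameters prefixed `true_`) and `trials` (one row per test trial with
#'   schedule and response columns, keyed by `participant_id` and `session`).
#' @export
make_cohort <- function(n_per_group = 20L,
                        group_presets = default_group_presets(),
                        covariate_model = default_covariate_model(),
                        sessions = 1L, seed = 1L,
                        schedule_args = list()) {
  if (is.null(names(n_per_group)) && length(n_per_group) == 1L) {
    n_per_group <- stats::setNames(rep(as.integer(n_per_group), 4L),
                                   GROUP_LEVELS)
  }
  groups <- names(n_per_group)
  if (!all(groups %in% names(group_presets))) {
    stop("missing preset for group(s): ",
         paste(setdiff(groups, names(group_presets)), collapse = ", "))
  }
  if (any(n_per_group < 1L)) stop("n_per_group must be >= 1")
  stopifnot(sessions %in% c(1L, 2L))
  set.seed(as.integer(seed))
  model <- covariate_model

  participants <- list()
  trials <- list()
  pid_counter <- 0L
  for (g in groups) {
    for (k in seq_len(n_per_group[[g]])) {
      pid_counter <- pid_counter + 1L
      pid <- sprintf("P%03d", pid_counter)
      s0 <- stats::rnorm(1, model$severity_mean[[g]], model$severity_sd)
      trait <- stats::rnorm(1, 0, model$trait_sd)
      centred <- s0 - model$severity_mean[[g]] + trait
      params <- individual_params(group_presets[[g]], centred, model)
      age <- stats::rnorm(1, model$age_mean[[g]], model$age_sd)
      education <- max(stats::rnorm(1, model$education_mean[[g]],
                                    model$education_sd), 6)
      gender <- if (stats::runif(1) < model$p_female) "F" else "M"
      outcomes0 <- latent_severity_link(s0, model)

      sev <- s0
      outcomes <- outcomes0
      for (ses in seq_len(sessions)) {
        if (ses > 1L) {
          sev <- sev + model$severity_progress_intercept +
            model$severity_progress_slope * s0 +
            stats::rnorm(1, 0, model$severity_progress_sd)
          outcomes <- latent_severity_link(sev, model)
        }
        ses_params <- apply_session_drift(params, ses)
        sched_seed <- sample.int(.Machine$integer.max, 1L)
        set.seed(sched_seed) # make_session_schedule reseeds anyway
        sched <- do.call(make_session_schedule,
                         c(list(seed = sched_seed), schedule_args))
        tr <- simulate_trial_responses(sched$test, ses_params)
        tr$participant_id <- pid
        tr$session <- ses
        trials[[length(trials) + 1L]] <- tr
        participants[[length(participants) + 1L]] <- data.frame(
          participant_id = pid, group = g, session = ses,
          age = age, gender = gender, education = education,
          ace = outcomes$ace, hv_mm3 = outcomes$hv_mm3,
          severity = sev,
          true_p_target = ses_params$p_target,
          true_p_misbind = ses_params$p_misbind,
          true_p_guess = ses_params$p_guess,
          true_sigma = ses_params$sigma,
          schedule_seed = sched_seed,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  participants <- do.call(rbind, participants)
  participants$group <- factor(participants$group, levels = GROUP_LEVELS)
  trials <- do.call(rbind, trials)
  first <- c("participant_id", "session")
  trials <- trials[, c(first, setdiff(names(trials), first))]
  list(participants = participants, trials = trials)
}

#' Write or read a simulated cohort as CSV files
#'
#' `participants.csv` holds one row per participant-session (covariates, ACE,
#' hippocampal volume, true generative parameters); `trials.csv` one row per
#' test trial. The round trip is lossless up to CSV numeric formatting.
#'
#' @param cohort A list as returned by [make_cohort()].
#' @param dir Output directory, created if needed.
#' @return `read_cohort_csv` returns a cohort list; `write_cohort_csv` the
#'   directory invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  participants <- utils::read.csv(file.path(dir, "participants.csv"))
  participants$group <- factor(participants$group, levels = GROUP_LEVELS)
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  validate_trials(trials)
  list(participants = participants, trials = trials)
}

# Schema check for trial logs; reports offending row numbers.
validate_trials <- function(trials) {
  required <- c("participant_id", "session", "trial_id", "set_size",
                "delay_s", "target_index", "identified_target",
                "response_x", "response_y",
                "identification_time_s", "localization_time_s")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!(trials$set_size %in% c(1L, 3L)))
  if (length(bad)) stop("invalid set_size at row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(trials$response_x < 0 | trials$response_x > 1 |
                 trials$response_y < 0 | trials$response_y > 1)
  if (length(bad)) stop("response location outside screen at row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(trials$target_index > trials$set_size)
  if (length(bad)) stop("target_index exceeds set_size at row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  invisible(trials)
}
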