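condition_key <- function(set_size, delay_s) {
  paste0("ss", set_size, "_d", delay_s)
}

CONDITION_KEYS <- c("ss1_d1", "ss1_d4", "ss3_d1", "ss3_d4")

#' Construct and validate generative mixture parameters
#'
#' The generative model mirrors the mixture structure of delayed-reproduction
#' responses: on a correctly identified trial the localization response comes
#' from one of three sources -- the target location (with isotropic Gaussian
#' imprecision of standard deviation `sigma`), the location of another item
#' in the memory array (misbinding, also with Gaussian imprecision), or a
#' uniform guess over the placement region. Identification success is
#' Bernoulli with a per-condition probability, and both response times are
#' lognormal.
#'
#' For 1-item trials misbinding is undefined (it requires at least two
#' objects), so `p_misbind` is reallocated proportionally to `p_target` and
#' `p_guess`.
#'
#' @param p_target,p_misbind,p_guess Mixture weights; must sum to 1.
#' @param sigma Localization imprecision SD, screen fractions.
#' @param p_identify Named numeric of identification probabilities for the
#'   four conditions (`ss1_d1`, `ss1_d4`, `ss3_d1`, `ss3_d4`), or a single
#'   number recycled to all four.
#' @param rt_ident_mu,rt_ident_sigma Lognormal meanlog/sdlog of the
#'   identification time (seconds).
#' @param rt_loc_mu,rt_loc_sigma Lognormal meanlog/sdlog of the localization
#'   (drag) time (seconds).
#' @param session_drift List of additive per-session changes applied at the
#'   second visit: `p_target` (probability scale), `sigma` (screen
#'   fractions), `p_identify` (probability scale, all conditions).
#' @return An object of class `omt_params`.
#' @export
generative_params <- function(p_target, p_misbind, p_guess, sigma,
                              p_identify,
                              rt_ident_mu = log(2), rt_ident_sigma = 0.35,
                              rt_loc_mu = log(2.5), rt_loc_sigma = 0.35,
                              session_drift = list(p_target = 0, sigma = 0,
                                                   p_identify = 0)) {
  if (length(p_identify) == 1L && is.null(names(p_identify))) {
    p_identify <- stats::setNames(rep(p_identify, 4L), CONDITION_KEYS)
  }
  p <- structure(
    list(
      p_target = p_target, p_misbind = p_misbind, p_guess = p_guess,
      sigma = sigma, p_identify = p_identify,
      rt_ident_mu = rt_ident_mu, rt_ident_sigma = rt_ident_sigma,
      rt_loc_mu = rt_loc_mu, rt_loc_sigma = rt_loc_sigma,
      session_drift = session_drift
    ),
    class = "omt_params"
  )
  validate_params(p)
  p
}

validate_params <- function(p) {
  probs <- c(p$p_target, p$p_misbind, p$p_guess)
  if (any(probs < 0 | probs > 1)) {
    stop("mixture weights must lie in [0, 1]")
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("p_target + p_misbind + p_guess must equal 1")
  }
  if (!is.numeric(p$sigma) || p$sigma <= 0) stop("sigma must be positive")
  if (!all(CONDITION_KEYS %in% names(p$p_identify))) {
    stop("p_identify must name all four conditions: ",
         paste(CONDITION_KEYS, collapse = ", "))
  }
  if (any(p$p_identify < 0 | p$p_identify > 1)) {
    stop("p_identify entries must lie in [0, 1]")
  }
  invisible(p)
}

#' Default generative presets for the four clinical groups
#'
#' Qualitatively ordered presets for elderly healthy controls (EHC),
#' subjective cognitive decline (SCD), mild cognitive impairment (MCI) and
#' Alzheimer's disease dementia (AD): target detection and identification
#' accuracy fall, while misbinding, guessing, imprecision and response times
#' rise, with increasing clinical severity. Identification accuracy also
#' falls with set size and delay. These are simulator settings for testing
#' the pipeline, not estimates from any real cohort.
#'
#' At the second visit the AD preset drifts (lower target detection and
#' identification accuracy, higher imprecision); the other groups are stable.
#'
#' @return Named list of `omt_params`, one per group, in severity order
#'   `EHC, SCD, MCI, AD`.
#' @export
default_group_presets <- function() {
  pid <- function(a, b, c, d) {
    stats::setNames(c(a, b, c, d), CONDITION_KEYS)
  }
  list(
    EHC = generative_params(0.80, 0.08, 0.12, sigma = 0.040,
                            p_identify = pid(0.98, 0.96, 0.90, 0.87),
                            rt_ident_mu = log(1.8), rt_loc_mu = log(2.2)),
    SCD = generative_params(0.78, 0.09, 0.13, sigma = 0.045,
                            p_identify = pid(0.97, 0.95, 0.88, 0.85),
                            rt_ident_mu = log(1.9), rt_loc_mu = log(2.3)),
    MCI = generative_params(0.68, 0.14, 0.18, sigma = 0.055,
                            p_identify = pid(0.92, 0.89, 0.78, 0.74),
                            rt_ident_mu = log(2.3), rt_loc_mu = log(2.7)),
    AD = generative_params(0.55, 0.18, 0.27, sigma = 0.070,
                           p_identify = pid(0.85, 0.80, 0.65, 0.60),
                           rt_ident_mu = log(2.9), rt_loc_mu = log(3.2),
                           session_drift = list(p_target = -0.07,
                                                sigma = 0.03,
                                                p_identify = -0.06))
  )
}

#' @export
print.omt_params <- function(x, ...) {
  cat(sprintf(
    "omt_params: target %.3f / misbind %.3f / guess %.3f, sigma %.3f\n",
    x$p_target, x$p_misbind, x$p_guess, x$sigma
  ))
  cat("  p_identify:", paste(sprintf("%s=%.2f", names(x$p_identify),
                                     x$p_identify), collapse = " "), "\n")
  invisible(x)
}

# Apply one session of drift; session 1 is the baseline parameters.
apply_session_drift <- function(params, session) {
  if (session <= 1L) return(params)
  d <- params$session_drift
  steps <- session - 1L
  params$p_target <- min(max(params$p_target + steps * d$p_target, 0), 1)
  excess <- 1 - params$p_target - params$p_misbind
  params$p_guess <- max(excess, 0)
  if (excess < 0) { # drift pushed p_target so high the rest must shrink
    params$p_misbind <- max(params$p_misbind + excess, 0)
    params$p_guess <- 1 - params$p_target - params$p_misbind
  }
  params$sigma <- max(params$sigma + steps * d$sigma, 1e-6)
  params$p_identify <- pmin(pmax(params$p_identify + steps * d$p_identify, 0), 1)
  validate_params(params)
  params
}

# Gaussian displacement truncated to the unit square by resampling.
truncated_gaussian_response <- function(centre_x, centre_y, sigma) {
  repeat {
    x <- stats::rnorm(1, centre_x, sigma)
    y <- stats::rnorm(1, centre_y, sigma)
    if (x >= 0 && x <= 1 && y >= 0 && y <= 1) return(c(x, y))
  }
}

#' Simulate one trial's response
#'
#' Identification succeeds with the condition's `p_identify`. On success the
#' localization response is drawn from the target / misbinding / guessing
#' mixture (misbinding mass reallocated proportionally on 1-item trials); on
#' failure the participant has chosen the foil and places it without
#' knowledge of the target, modelled as a uniform draw over the placement
#' region. The true generating component is recorded for parameter-recovery
#' checks (`"none"` when identification failed).
#'
#' @param trial_row One row of a schedule data frame.
#' @param params An `omt_params` object.
#' @param margin Edge margin of the guessing region, matching the schedule.
#' @return One-row data frame: `identified_target`, `response_x`,
#'   `response_y`, `identification_time_s`, `localization_time_s`,
#'   `true_component`.
#' @export
sample_response <- function(trial_row, params, margin = 0.10) {
  validate_params(params)
  key <- condition_key(trial_row$set_size, trial_row$delay_s)
  identified <- stats::runif(1) < params$p_identify[[key]]

  if (!identified) {
    component <- "none"
    resp <- c(stats::runif(1, margin, 1 - margin),
              stats::runif(1, margin, 1 - margin))
  } else {
    w <- c(target = params$p_target, misbind = params$p_misbind,
           guess = params$p_guess)
    if (trial_row$set_size == 1L) {
      w["misbind"] <- 0
      w <- w / sum(w)
    }
    component <- sample(names(w), 1L, prob = w)
    locs <- trial_item_locations(trial_row)
    ti <- trial_row$target_index
    resp <- switch(component,
      target = truncated_gaussian_response(locs[ti, 1], locs[ti, 2],
                                           params$sigma),
      misbind = {
        others <- setdiff(seq_len(nrow(locs)), ti)
        pick <- if (length(others) == 1L) others else sample(others, 1L)
        truncated_gaussian_response(locs[pick, 1], locs[pick, 2],
                                    params$sigma)
      },
      guess = c(stats::runif(1, margin, 1 - margin),
                stats::runif(1, margin, 1 - margin))
    )
  }
  data.frame(
    identified_target = identified,
    response_x = resp[1], response_y = resp[2],
    identification_time_s = stats::rlnorm(1, params$rt_ident_mu,
                                          params$rt_ident_sigma),
    localization_time_s = stats::rlnorm(1, params$rt_loc_mu,
                                        params$rt_loc_sigma),
    true_component = component,
    stringsAsFactors = FALSE
  )
}

#' Simulate responses for a whole schedule
#'
#' Vectorized application of the generative model in [sample_response()] to
#' every row of a test schedule.
#'
#' @param schedule_test Test-trial data frame from [make_session_schedule()].
#' @param params An `omt_params` object.
#' @param margin Edge margin of the guessing region.
#' @return `schedule_test` with the response columns appended.
#' @export
simulate_trial_responses <- function(schedule_test, params, margin = 0.10) {
  validate_params(params)
  n <- nrow(schedule_test)
  key <- condition_key(schedule_test$set_size, schedule_test$delay_s)
  identified <- stats::runif(n) < params$p_identify[key]

  comp <- character(n)
  rx <- numeric(n)
  ry <- numeric(n)
  for (i in seq_len(n)) {
    if (!identified[i]) {
      comp[i] <- "none"
      rx[i] <- stats::runif(1, margin, 1 - margin)
      ry[i] <- stats::runif(1, margin, 1 - margin)
      next
    }
    w <- c(target = params$p_target, misbind = params$p_misbind,
           guess = params$p_guess)
    if (schedule_test$set_size[i] == 1L) {
      w["misbind"] <- 0
      w <- w / sum(w)
    }
    comp[i] <- sample(names(w), 1L, prob = w)
    if (comp[i] == "guess") {
      rx[i] <- stats::runif(1, margin, 1 - margin)
      ry[i] <- stats::runif(1, margin, 1 - margin)
    } else {
      ti <- schedule_test$target_index[i]
      ci <- if (comp[i] == "target") ti else {
        others <- setdiff(seq_len(schedule_test$set_size[i]), ti)
        if (length(others) == 1L) others else sample(others, 1L)
      }
      cx <- schedule_test[[paste0("item", ci, "_x")]][i]
      cy <- schedule_test[[paste0("item", ci, "_y")]][i]
      r <- truncated_gaussian_response(cx, cy, params$sigma)
      rx[i] <- r[1]
      ry[i] <- r[2]
    }
  }
  schedule_test$identified_target <- identified
  schedule_test$response_x <- rx
  schedule_test$response_y <- ry
  schedule_test$identification_time_s <-
    stats::rlnorm(n, params$rt_ident_mu, params$rt_ident_sigma)
  schedule_test$localization_time_s <-
    stats::rlnorm(n, params$rt_loc_mu, params$rt_loc_sigma)
  schedule_test$true_component <- comp
  schedule_test
}
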