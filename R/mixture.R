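#' Permutation-based attribution of a single localization response
#'
#' Classifies one trial's localization response among three sources by
#' repeated nearest-location comparison. On each of `n_reps` repetitions one
#' location is drawn uniformly (with replacement) from a pool of item
#' locations taken from the participant's other trials, and the response is
#' assigned to whichever of (1) the target location, (2) the nearest
#' non-probed item of the same trial, or (3) the drawn other-trial location
#' is closest. The returned proportions are classification counts divided by
#' `n_reps`: responses near the target count as target detection, responses
#' near an in-trial item as misbinding, and responses that even a random
#' other-trial location can beat as uniform guessing.
#'
#' Ties are broken with priority target > in-trial distractor > random draw
#' (they have probability zero for continuous responses; the rule fixes
#' determinism). For 1-item trials there is no in-trial distractor and the
#' misbinding proportion is exactly zero.
#'
#' @param response_loc,target_loc Numeric `c(x, y)` in screen fractions.
#' @param in_trial_distractors Matrix with columns x, y of the trial's
#'   non-probed item locations (zero rows for set size 1).
#' @param other_trial_pool Matrix with columns x, y of item locations from
#'   other trials; must be non-empty.
#' @param n_reps Number of pool draws (5000 by default).
#' @return A one-row data frame: `p_target_hat`, `p_misbind_hat`,
#'   `p_guess_hat` (summing to 1 exactly), `n_reps`, `d_target`,
#'   `d_nearest_distractor` (`NA` for set size 1).
#' @seealso [exact_attribution()] for the deterministic expectation over the
#'   pool.
#' @export
attribute_trial <- function(response_loc, target_loc, in_trial_distractors,
                            other_trial_pool, n_reps = 5000L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  pool <- as.matrix(other_trial_pool)
  if (nrow(pool) == 0L) stop("other_trial_pool is empty")
  draws <- pool[sample.int(nrow(pool), n_reps, replace = TRUE), ,
                drop = FALSE]
  attribution_from_draws(response_loc, target_loc, in_trial_distractors,
                         draws, n_reps)
}

#' Exact expectation of the permutation attribution
#'
#' The only randomness in [attribute_trial()] is the uniform pool draw, so
#' its expectation is obtained by enumerating every pool element exactly
#' once. This is deterministic, exact and faster than 5000 repetitions; it
#' serves as the analytic oracle for the permutation estimator and as a
#' drop-in alternative.
#'
#' @inheritParams attribute_trial
#' @return As [attribute_trial()], with `n_reps` set to the pool size.
#' @export
exact_attribution <- function(response_loc, target_loc, in_trial_distractors,
                              other_trial_pool) {
  pool <- as.matrix(other_trial_pool)
  if (nrow(pool) == 0L) stop("other_trial_pool is empty")
  attribution_from_draws(response_loc, target_loc, in_trial_distractors,
                         pool, nrow(pool))
}

attribution_from_draws <- function(response_loc, target_loc,
                                   in_trial_distractors, draws, n_reps) {
  d1 <- euclid(response_loc[1], response_loc[2], target_loc[1], target_loc[2])
  dis <- as.matrix(in_trial_distractors)
  d2 <- if (nrow(dis) == 0L) Inf else {
    min(euclid(response_loc[1], response_loc[2], dis[, 1], dis[, 2]))
  }
  d3 <- euclid(response_loc[1], response_loc[2], draws[, 1], draws[, 2])
  is_target <- d1 <= d2 & d1 <= d3
  is_misbind <- !is_target & d2 <= d3
  n_target <- sum(is_target)
  n_misbind <- sum(is_misbind)
  data.frame(
    p_target_hat = n_target / n_reps,
    p_misbind_hat = n_misbind / n_reps,
    p_guess_hat = (n_reps - n_target - n_misbind) / n_reps,
    n_reps = n_reps,
    d_target = d1,
    d_nearest_distractor = if (is.finite(d2)) d2 else NA_real_
  )
}

# Weighted standard deviation (normalized weights, population form).
weighted_sd <- function(x, w) {
  if (sum(w) <= 0) return(NA_real_)
  m <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

#' Mixture-model metrics for one participant-session
#'
#' Applies the per-trial attribution to every correctly identified test
#' trial. For each trial the pool of "random" locations holds all item
#' locations of the participant's other test trials. Trial attributions are
#' averaged within each (set size, delay) condition, and the cumulative
#' metrics are the unweighted means across conditions: target detection and
#' guessing over all four conditions, misbinding over the two 3-item
#' conditions only (it cannot occur with a single item). Imprecision is the
#' response-to-target radial deviation weighted by each trial's target
#' attribution, aggregated the same way (per-condition weighted SD, then
#' mean across the four conditions).
#'
#' @param trials Data frame of one participant-session's test trials.
#' @param n_reps Pool draws per trial for the permutation estimator.
#' @param method `"permutation"` (the reference procedure) or `"exact"`
#'   (deterministic pool enumeration, identical in expectation).
#' @return A one-row data frame: `target_detection`, `misbinding`,
#'   `guessing`, `imprecision`, `n_trials_used`, plus per-condition columns
#'   `td_ss{s}_d{d}`, `mb_ss3_d{d}`, `gs_ss{s}_d{d}`, `impr_ss{s}_d{d}`.
#'   `NA` metrics with a warning when no trial was correctly identified.
#' @export
participant_mixture <- function(trials, n_reps = 5000L,
                                method = c("permutation", "exact")) {
  method <- match.arg(method)
  ok <- trials[trials$identified_target, , drop = FALSE]
  if (nrow(ok) == 0L) {
    warning("no correctly identified trials; mixture estimate is NA")
    return(data.frame(target_detection = NA_real_, misbinding = NA_real_,
                      guessing = NA_real_, imprecision = NA_real_,
                      n_trials_used = 0L))
  }
  # pool: all item locations of all trials, indexed by source trial
  all_locs <- trial_location_pool(trials)
  att <- vector("list", nrow(ok))
  for (i in seq_len(nrow(ok))) {
    row <- ok[i, , drop = FALSE]
    k <- row$set_size
    locs <- trial_item_locations(row)
    ti <- row$target_index
    pool <- all_locs[all_locs[, "trial"] != row$trial_id, c("x", "y"),
                     drop = FALSE]
    resp <- c(row$response_x, row$response_y)
    att[[i]] <- if (method == "exact") {
      exact_attribution(resp, locs[ti, ], locs[-ti, , drop = FALSE], pool)
    } else {
      attribute_trial(resp, locs[ti, ], locs[-ti, , drop = FALSE], pool,
                      n_reps)
    }
  }
  att <- do.call(rbind, att)
  att$set_size <- ok$set_size
  att$delay_s <- ok$delay_s
  att$radial_error <- target_error(ok)

  conds <- expand.grid(set_size = c(1L, 3L), delay_s = c(1, 4))
  td <- mb <- gs <- impr <- rep(NA_real_, 4L)
  for (r in seq_len(4L)) {
    sub <- att[att$set_size == conds$set_size[r] &
                 att$delay_s == conds$delay_s[r], , drop = FALSE]
    if (nrow(sub) == 0L) next
    td[r] <- mean(sub$p_target_hat)
    gs[r] <- mean(sub$p_guess_hat)
    if (conds$set_size[r] == 3L) mb[r] <- mean(sub$p_misbind_hat)
    impr[r] <- weighted_sd(sub$radial_error, sub$p_target_hat)
  }
  # cumulative means run over the conditions that contributed correct trials
  out <- data.frame(
    target_detection = mean(td, na.rm = TRUE),
    misbinding = mean(mb[conds$set_size == 3L], na.rm = TRUE),
    guessing = mean(gs, na.rm = TRUE),
    imprecision = mean(impr, na.rm = TRUE),
    n_trials_used = nrow(ok)
  )
  out$misbinding[is.nan(out$misbinding)] <- NA_real_
  cond_names <- paste0("ss", conds$set_size, "_d", conds$delay_s)
  for (r in seq_len(4L)) {
    out[[paste0("td_", cond_names[r])]] <- td[r]
    out[[paste0("gs_", cond_names[r])]] <- gs[r]
    out[[paste0("impr_", cond_names[r])]] <- impr[r]
    if (conds$set_size[r] == 3L) out[[paste0("mb_", cond_names[r])]] <- mb[r]
  }
  out
}

# All item locations of a trial table as a matrix with their trial ids.
trial_location_pool <- function(trials) {
  pieces <- list()
  for (i in 1:3) {
    xs <- trials[[paste0("item", i, "_x")]]
    keep <- !is.na(xs)
    if (!any(keep)) next
    pieces[[i]] <- cbind(trial = trials$trial_id[keep], x = xs[keep],
                         y = trials[[paste0("item", i, "_y")]][keep])
  }
  do.call(rbind, pieces)
}

#' All eight per-participant metrics for a cohort
#'
#' Convenience scorer: computes the four cumulative basic metrics and the
#' four mixture metrics for every participant-session of a cohort trial
#' table.
#'
#' @param trials Cohort trial table (as in [make_cohort()]`$trials`).
#' @param n_reps,method Passed to [participant_mixture()].
#' @param mixture Set `FALSE` to skip the (more expensive) mixture
#'   decomposition and return the basic metrics only.
#' @return Data frame with one row per participant-session: keys,
#'   `identification_accuracy`, `abs_localization_error`,
#'   `identification_time_s`, `localization_time_s`, `target_detection`,
#'   `misbinding`, `guessing`, `imprecision`, `n_trials_used`, and
#'   per-condition columns.
#' @export
score_cohort <- function(trials, n_reps = 5000L,
                         method = c("permutation", "exact"),
                         mixture = TRUE) {
  method <- match.arg(method)
  keys <- unique(trials[, c("participant_id", "session")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- trials[trials$participant_id == keys$participant_id[i] &
                    trials$session == keys$session[i], , drop = FALSE]
    pc <- per_condition_metrics(sub)
    basic <- suppressWarnings(cumulative_metrics(pc))
    mix <- if (mixture) {
      suppressWarnings(participant_mixture(sub, n_reps, method))
    } else {
      data.frame(row.names = 1L)
    }
    cond_cols <- stats::setNames(
      as.list(c(pc$identification_accuracy, pc$abs_localization_error)),
      c(paste0("ia_ss", pc$set_size, "_d", pc$delay_s),
        paste0("ale_ss", pc$set_size, "_d", pc$delay_s))
    )
    rows[[i]] <- cbind(keys[i, , drop = FALSE], basic, mix,
                       as.data.frame(cond_cols))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
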