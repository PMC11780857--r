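# Shared builders for small in-code fixtures.

# A minimal trial table with full control over geometry and responses.
# Defaults: one 3-item trial, response exactly on the target.
toy_trials <- function(n = 1L, set_size = 3L, delay_s = 1,
                       identified = TRUE,
                       response_on = c("target", "distractor")) {
  response_on <- match.arg(response_on)
  base_locs <- matrix(c(0.3, 0.3, 0.7, 0.3, 0.5, 0.8), ncol = 2,
                      byrow = TRUE)
  out <- NULL
  for (i in seq_len(n)) {
    # vary geometry a little per trial so pools are not degenerate
    shift <- 0.02 * ((i - 1) %% 5)
    locs <- pmin(base_locs + shift, 0.9)
    row <- data.frame(trial_id = i, block = 1L, set_size = set_size,
                      delay_s = delay_s, target_index = 1L)
    for (k in 1:3) {
      row[[paste0("item", k, "_shape")]] <- if (k <= set_size) k else NA_integer_
      row[[paste0("item", k, "_colour")]] <- if (k <= set_size) 0L else NA_integer_
      row[[paste0("item", k, "_x")]] <- if (k <= set_size) locs[k, 1] else NA_real_
      row[[paste0("item", k, "_y")]] <- if (k <= set_size) locs[k, 2] else NA_real_
    }
    row$foil_shape <- 99L
    row$foil_colour <- 0L
    resp <- if (response_on == "target") locs[1, ] else locs[2, ]
    row$identified_target <- identified
    row$response_x <- resp[1]
    row$response_y <- resp[2]
    row$identification_time_s <- 1.5
    row$localization_time_s <- 2.5
    row$true_component <- if (identified) "target" else "none"
    out <- rbind(out, row)
  }
  out
}

# Simulate one participant-session under explicit mixture settings.
simulate_participant <- function(seed, p_target, p_misbind, p_guess, sigma,
                                 p_identify = 0.9, n_trials_scale = 1L) {
  params <- generative_params(p_target, p_misbind, p_guess, sigma,
                              p_identify = p_identify)
  sched <- make_session_schedule(
    seed, trials_per_condition_per_block = 10L * n_trials_scale
  )
  simulate_trial_responses(sched$test, params)
}

# Random attribution geometry for oracle comparisons.
random_geometry <- function(pool_size = 25L) {
  list(
    response = stats::runif(2, 0.05, 0.95),
    target = stats::runif(2, 0.05, 0.95),
    distractors = matrix(stats::runif(4, 0.05, 0.95), ncol = 2),
    pool = matrix(stats::runif(2 * pool_size, 0.05, 0.95), ncol = 2)
  )
}
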