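euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

# Distance from each response to its trial's target location.
target_error <- function(trials) {
  k <- trials$target_index
  tx <- numeric(nrow(trials))
  ty <- numeric(nrow(trials))
  for (i in 1:3) {
    sel <- k == i
    tx[sel] <- trials[[paste0("item", i, "_x")]][sel]
    ty[sel] <- trials[[paste0("item", i, "_y")]][sel]
  }
  euclid(trials$response_x, trials$response_y, tx, ty)
}

#' Basic performance metrics
#'
#' The four basic metrics of the task: identification accuracy (proportion of
#' trials on which the target object was correctly identified), absolute
#' localization error (mean Euclidean distance between the original item
#' location and the response location, in screen fractions), and the mean
#' identification and localization times in seconds. Localization error and
#' both times are computed only over correctly identified trials, matching
#' the convention used for the mixture metrics.
#'
#' @param trials Data frame of test trials with response columns (one
#'   participant-session).
#' @return `identification_accuracy`: a proportion.
#'   `absolute_localization_error`: mean error, or `NA` with a warning when
#'   no trial was correctly identified. `response_times`: named vector
#'   `c(identification_time_s, localization_time_s)`.
#' @export
identification_accuracy <- function(trials) {
  if (nrow(trials) == 0L) stop("no trials supplied")
  mean(trials$identified_target)
}

#' @rdname identification_accuracy
#' @export
absolute_localization_error <- function(trials) {
  ok <- trials[trials$identified_target, , drop = FALSE]
  if (nrow(ok) == 0L) {
    warning("no correctly identified trials; localization error is NA")
    return(NA_real_)
  }
  mean(target_error(ok))
}

#' @rdname identification_accuracy
#' @export
response_times <- function(trials) {
  ok <- trials[trials$identified_target, , drop = FALSE]
  if (nrow(ok) == 0L) {
    warning("no correctly identified trials; response times are NA")
    return(c(identification_time_s = NA_real_,
             localization_time_s = NA_real_))
  }
  c(identification_time_s = mean(ok$identification_time_s),
    localization_time_s = mean(ok$localization_time_s))
}

#' Per-condition and cumulative basic metrics
#'
#' `per_condition_metrics` evaluates the four basic metrics within each of
#' the four (set size x delay) conditions. `cumulative_metrics` averages the
#' per-condition values with equal weight per condition (the task's standard
#' cumulative measure); a condition with a missing value propagates `NA`
#' with a warning.
#'
#' @param trials Data frame of one participant-session's test trials.
#' @return `per_condition_metrics`: a data frame with one row per condition
#'   (`set_size`, `delay_s`, `n_trials`, `n_correct`, the four metrics).
#'   `cumulative_metrics`: a one-row data frame of the four cumulative basic
#'   metrics.
#' @export
per_condition_metrics <- function(trials) {
  conds <- expand.grid(set_size = c(1L, 3L), delay_s = c(1, 4))
  out <- conds
  out$n_trials <- NA_integer_
  out$n_correct <- NA_integer_
  out$identification_accuracy <- NA_real_
  out$abs_localization_error <- NA_real_
  out$identification_time_s <- NA_real_
  out$localization_time_s <- NA_real_
  for (r in seq_len(nrow(conds))) {
    sub <- trials[trials$set_size == conds$set_size[r] &
                    trials$delay_s == conds$delay_s[r], , drop = FALSE]
    if (nrow(sub) == 0L) next
    out$n_trials[r] <- nrow(sub)
    out$n_correct[r] <- sum(sub$identified_target)
    out$identification_accuracy[r] <- identification_accuracy(sub)
    if (out$n_correct[r] > 0L) {
      out$abs_localization_error[r] <- absolute_localization_error(sub)
      rt <- response_times(sub)
      out$identification_time_s[r] <- rt[["identification_time_s"]]
      out$localization_time_s[r] <- rt[["localization_time_s"]]
    }
  }
  out
}

#' @rdname per_condition_metrics
#' @param condition_metrics Output of `per_condition_metrics`.
#' @export
cumulative_metrics <- function(condition_metrics) {
  cols <- c("identification_accuracy", "abs_localization_error",
            "identification_time_s", "localization_time_s")
  vals <- vapply(cols, function(cl) {
    v <- condition_metrics[[cl]]
    if (anyNA(v)) {
      warning("condition with missing ", cl,
              "; cumulative value is NA")
      return(NA_real_)
    }
    mean(v)
  }, numeric(1))
  as.data.frame(as.list(vals))
}
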