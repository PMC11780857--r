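#' Build the fractal stimulus library
#'
#' The task draws its stimuli from a fixed library of 196 fractal images:
#' 49 distinct shapes, each in 4 colour variants. Stimuli are identified
#' here by their `(shape_id, colour_id)` pair; the actual images are never
#' rendered.
#'
#' @return A data frame with 196 rows and columns `shape_id` (0--48) and
#'   `colour_id` (0--3), in deterministic shape-major order.
#' @examples
#' lib <- build_stimulus_library()
#' nrow(lib) # 196
#' @export
build_stimulus_library <- function() {
  data.frame(
    shape_id = rep(0:48, each = 4L),
    colour_id = rep(0:3, times = 49L)
  )
}

# Rejection-sample `n` item locations in [margin, 1 - margin]^2 with all
# pairwise distances >= min_separation. Errors out when the budget is spent.
sample_item_locations <- function(n, min_separation = 0.15, margin = 0.10,
                                  max_attempts = 10000L) {
  lo <- margin
  hi <- 1 - margin
  if (hi <= lo) stop("margin leaves no placement region")
  for (attempt in seq_len(max_attempts)) {
    x <- stats::runif(n, lo, hi)
    y <- stats::runif(n, lo, hi)
    if (n == 1L) return(cbind(x = x, y = y))
    d <- stats::dist(cbind(x, y))
    if (min(d) >= min_separation) return(cbind(x = x, y = y))
  }
  stop(sprintf(
    "could not place %d items with min_separation = %.3f in %d attempts",
    n, min_separation, max_attempts
  ))
}

# One block's worth of trial rows (wide format, up to 3 items per trial).
empty_schedule_frame <- function(n) {
  out <- data.frame(
    trial_id = integer(n), block = integer(n),
    set_size = integer(n), delay_s = numeric(n),
    target_index = integer(n)
  )
  for (i in 1:3) {
    out[[paste0("item", i, "_shape")]] <- rep(NA_integer_, n)
    out[[paste0("item", i, "_colour")]] <- rep(NA_integer_, n)
    out[[paste0("item", i, "_x")]] <- rep(NA_real_, n)
    out[[paste0("item", i, "_y")]] <- rep(NA_real_, n)
  }
  out$foil_shape <- integer(n)
  out$foil_colour <- integer(n)
  out
}

fill_trial_row <- function(frame, row, block, set_size, delay_s, library,
                           min_separation, margin, max_attempts) {
  locs <- sample_item_locations(set_size, min_separation, margin, max_attempts)
  items <- sample.int(nrow(library), set_size)
  frame$block[row] <- block
  frame$set_size[row] <- set_size
  frame$delay_s[row] <- delay_s
  frame$target_index[row] <- sample.int(set_size, 1L)
  for (i in seq_len(set_size)) {
    frame[[paste0("item", i, "_shape")]][row] <- library$shape_id[items[i]]
    frame[[paste0("item", i, "_colour")]][row] <- library$colour_id[items[i]]
    frame[[paste0("item", i, "_x")]][row] <- locs[i, "x"]
    frame[[paste0("item", i, "_y")]][row] <- locs[i, "y"]
  }
  foil <- sample(setdiff(seq_len(nrow(library)), items), 1L)
  frame$foil_shape[row] <- library$shape_id[foil]
  frame$foil_colour[row] <- library$colour_id[foil]
  frame
}

#' Generate a pseudorandom session schedule
#'
#' A session is a practice block followed by `blocks` test blocks. Each test
#' block crosses set size (1 or 3 items) with delay (1 s or 4 s) and contains
#' `trials_per_condition_per_block` trials of each of the four conditions in
#' randomly permuted order. Item locations are rejection-sampled in the
#' normalized screen square `[0, 1]^2` (origin top-left) within an edge
#' margin and with a minimum pairwise separation; the foil is drawn from the
#' stimulus library excluding the trial's own items.
#'
#' With the defaults this yields 8 practice trials and
#' 120 = 10 x 4 conditions x 3 blocks test trials.
#'
#' @param seed Integer seed; identical seeds give bit-identical schedules.
#' @param blocks Number of test blocks.
#' @param trials_per_condition_per_block Trials per (set size, delay) cell
#'   per block.
#' @param practice_trials Number of practice trials (conditions cycled, order
#'   shuffled).
#' @param min_separation Minimum pairwise item distance, screen fractions.
#' @param margin Edge margin of the placement region, screen fractions.
#' @param max_attempts Rejection-sampling budget per trial.
#' @return A list with data frames `practice` and `test`, one row per trial
#'   (columns: `trial_id`, `block`, `set_size`, `delay_s`, `target_index`,
#'   `item{1..3}_{shape,colour,x,y}`, `foil_shape`, `foil_colour`). Practice
#'   trials carry `block = 0`.
#' @export
make_session_schedule <- function(seed, blocks = 3L,
                                  trials_per_condition_per_block = 10L,
                                  practice_trials = 8L,
                                  min_separation = 0.15, margin = 0.10,
                                  max_attempts = 10000L) {
  stopifnot(blocks >= 1L, trials_per_condition_per_block >= 1L,
            practice_trials >= 0L)
  set.seed(as.integer(seed))
  library <- build_stimulus_library()
  conditions <- expand.grid(set_size = c(1L, 3L), delay_s = c(1, 4))

  n_test <- blocks * 4L * trials_per_condition_per_block
  test <- empty_schedule_frame(n_test)
  row <- 0L
  for (b in seq_len(blocks)) {
    cond_idx <- sample(rep(seq_len(4L), trials_per_condition_per_block))
    for (ci in cond_idx) {
      row <- row + 1L
      test <- fill_trial_row(
        test, row, b, conditions$set_size[ci], conditions$delay_s[ci],
        library, min_separation, margin, max_attempts
      )
    }
  }
  test$trial_id <- seq_len(n_test)

  practice <- empty_schedule_frame(practice_trials)
  if (practice_trials > 0L) {
    cond_idx <- sample(rep_len(seq_len(4L), practice_trials))
    for (r in seq_len(practice_trials)) {
      practice <- fill_trial_row(
        practice, r, 0L, conditions$set_size[cond_idx[r]],
        conditions$delay_s[cond_idx[r]], library,
        min_separation, margin, max_attempts
      )
    }
    practice$trial_id <- seq_len(practice_trials)
  }
  list(practice = practice, test = test)
}

# Matrix of a trial's item locations (set_size x 2), from a wide schedule row.
trial_item_locations <- function(trial_row) {
  k <- trial_row$set_size
  cbind(
    x = as.numeric(trial_row[paste0("item", seq_len(k), "_x")]),
    y = as.numeric(trial_row[paste0("item", seq_len(k), "_y")])
  )
}

#' Write or read a schedule as CSV
#'
#' One row per trial with a `phase` column (`practice`/`test`); all other
#' columns as produced by [make_session_schedule()]. The round trip is
#' lossless.
#'
#' @param schedule A list with `practice` and `test` data frames.
#' @param path File path.
#' @return `read_schedule_csv` returns a schedule list; `write_schedule_csv`
#'   returns `path` invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  prac <- schedule$practice
  test <- schedule$test
  prac$phase <- if (nrow(prac)) "practice" else character(0)
  test$phase <- "test"
  out <- rbind(prac, test)
  out <- out[, c("phase", setdiff(names(out), "phase"))]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path)
  list(
    practice = df[df$phase == "practice", setdiff(names(df), "phase"),
                  drop = FALSE],
    test = df[df$phase == "test", setdiff(names(df), "phase"), drop = FALSE]
  )
}
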