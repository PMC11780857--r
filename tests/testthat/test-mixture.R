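test_that("a response on the target is always attributed to the target", {
  pool <- matrix(stats::runif(40), ncol = 2)
  att <- attribute_trial(c(0.4, 0.4), c(0.4, 0.4),
                         matrix(c(0.8, 0.8), ncol = 2), pool, n_reps = 500)
  expect_equal(att$p_target_hat, 1.0)
  expect_equal(att$d_target, 0)
})

test_that("1-item trials cannot produce misbinding attributions", {
  pool <- matrix(stats::runif(40), ncol = 2)
  none <- matrix(numeric(0), ncol = 2)
  att <- attribute_trial(c(0.2, 0.9), c(0.6, 0.6), none, pool, n_reps = 200)
  expect_equal(att$p_misbind_hat, 0)
  expect_true(is.na(att$d_nearest_distractor))
  ex <- exact_attribution(c(0.2, 0.9), c(0.6, 0.6), none, pool)
  expect_equal(ex$p_misbind_hat, 0)
})

test_that("attribution proportions always sum to exactly one", {
  set.seed(201)
  for (i in 1:25) {
    g <- random_geometry()
    att <- attribute_trial(g$response, g$target, g$distractors, g$pool,
                           n_reps = 137)
    expect_identical(att$p_target_hat + att$p_misbind_hat + att$p_guess_hat,
                     1)
    ex <- exact_attribution(g$response, g$target, g$distractors, g$pool)
    expect_identical(ex$p_target_hat + ex$p_misbind_hat + ex$p_guess_hat, 1)
  }
})

test_that("enumeration is the exact expectation of the permutation draw", {
  # fixed geometry from a hand-checkable configuration
  target <- c(0.5, 0.5)
  distractor <- matrix(c(0.9, 0.9), ncol = 2)
  response <- c(0.85, 0.85)
  pool <- matrix(c(0.1, 0.1, 0.5, 0.85), ncol = 2, byrow = TRUE)
  ex <- exact_attribution(response, target, distractor, pool)
  # d(resp, target) = .495; d(resp, distractor) = .0707 beats both pool
  # points (1.06 and .35): every draw is attributed to the distractor
  expect_equal(ex$p_misbind_hat, 1.0)
  expect_equal(ex$p_guess_hat, 0.0)
  set.seed(202)
  att <- attribute_trial(response, target, distractor, pool, n_reps = 5000)
  expect_equal(att$p_misbind_hat, 1.0)

  # exact tie on binary-fraction distances: distractor beats the pool draw
  tie <- exact_attribution(c(0.5, 0.5), c(0.25, 0.25) + 10,
                           matrix(c(0.75, 0.5), ncol = 2),
                           matrix(c(0.25, 0.5), ncol = 2))
  expect_equal(tie$p_misbind_hat, 1.0)

  # pool of one element: permutation equals enumeration exactly
  one <- matrix(c(0.52, 0.55), ncol = 2)
  ex1 <- exact_attribution(response, target, distractor, one)
  at1 <- attribute_trial(response, target, distractor, one, n_reps = 17)
  expect_equal(at1[, 1:3], ex1[, 1:3])

  # random geometries: 5000-rep estimate near the enumerated expectation
  set.seed(203)
  for (i in 1:30) {
    g <- random_geometry()
    ex <- exact_attribution(g$response, g$target, g$distractors, g$pool)
    at <- attribute_trial(g$response, g$target, g$distractors, g$pool,
                          n_reps = 5000)
    for (comp in c("p_target_hat", "p_misbind_hat", "p_guess_hat")) {
      p <- ex[[comp]]
      se <- sqrt(p * (1 - p) / 5000)
      expect_lt(abs(at[[comp]] - p), max(3 * se, 1e-9))
    }
  }
})

test_that("errors are raised for empty pools and bad repetition counts", {
  none <- matrix(numeric(0), ncol = 2)
  expect_error(attribute_trial(c(.5, .5), c(.4, .4), none, none, 100),
               "pool")
  pool <- matrix(stats::runif(10), ncol = 2)
  expect_error(attribute_trial(c(.5, .5), c(.4, .4), none, pool, 0),
               "n_reps")
})

test_that("perfect responses give a pure target decomposition", {
  tr <- toy_trials(20)
  est <- participant_mixture(tr, method = "exact")
  expect_equal(est$target_detection, 1.0)
  expect_equal(est$misbinding, 0.0)
  expect_equal(est$guessing, 0.0)
  expect_equal(est$imprecision, 0.0)
  expect_equal(est$n_trials_used, 20L)
})

test_that("mixture estimates need correct trials and a seeded rng", {
  tr <- toy_trials(5, identified = FALSE)
  expect_warning(est <- participant_mixture(tr), "no correctly")
  expect_true(is.na(est$target_detection))
  tr <- simulate_participant(204, 0.7, 0.15, 0.15, 0.05)
  set.seed(99)
  a <- participant_mixture(tr, n_reps = 300)
  set.seed(99)
  b <- participant_mixture(tr, n_reps = 300)
  expect_identical(a, b)
})

test_that("estimated misbinding tracks the generative misbinding rate", {
  # higher generative swap rate must yield higher estimated misbinding
  for (seed in 205:207) {
    hi <- simulate_participant(seed, 0.70, 0.15, 0.15, 0.04,
                               p_identify = 1, n_trials_scale = 5L)
    lo <- simulate_participant(seed + 50, 0.85, 0.00, 0.15, 0.04,
                               p_identify = 1, n_trials_scale = 5L)
    est_hi <- participant_mixture(hi, method = "exact")
    est_lo <- participant_mixture(lo, method = "exact")
    expect_gt(est_hi$misbinding, est_lo$misbinding)
  }
})
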