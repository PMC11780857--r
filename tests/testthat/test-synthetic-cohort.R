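test_that("generative parameter validation rejects inconsistent settings", {
  expect_error(generative_params(0.5, 0.3, 0.3, 0.05, 0.9), "equal 1")
  expect_error(generative_params(0.8, 0.1, 0.1, -1, 0.9), "sigma")
  expect_error(generative_params(0.8, 0.1, 0.1, 0.05,
                                 c(ss1_d1 = 0.9)), "p_identify")
  p <- default_group_presets()
  for (g in p) {
    expect_equal(g$p_target + g$p_misbind + g$p_guess, 1, tolerance = 1e-12)
  }
})

test_that("degenerate mixtures behave as point mass and uniform limits", {
  sch <- make_session_schedule(5)
  # pure guessing: x coordinates uniform over the placement region
  guess <- generative_params(0, 0, 1, sigma = 0.05, p_identify = 1)
  set.seed(1)
  rows <- sch$test[rep(1:120, length.out = 10000L), ]
  tr <- simulate_trial_responses(rows, guess)
  ks <- stats::ks.test(tr$response_x, "punif", 0.10, 0.90)
  expect_gt(ks$p.value, 0.01)
  # near-deterministic target: response collapses onto the target location
  point <- generative_params(1, 0, 0, sigma = 1e-6, p_identify = 1)
  set.seed(2)
  tr <- simulate_trial_responses(sch$test, point)
  err <- suppressWarnings(absolute_localization_error(tr))
  expect_lt(max(abs(err)), 1e-4)
})

test_that("misbinding never occurs on 1-item trials", {
  sch <- make_session_schedule(6)
  ones <- sch$test[sch$test$set_size == 1L, ]
  params <- generative_params(0.1, 0.8, 0.1, sigma = 0.05, p_identify = 1)
  set.seed(3)
  tr <- simulate_trial_responses(ones[rep(1:nrow(ones), 20), ], params)
  expect_false(any(tr$true_component == "misbind"))
})

test_that("simulated component frequencies match the generative weights", {
  # >= 50,000 correct-identification 3-item trials; 3 binomial SEs
  sch <- make_session_schedule(8)
  threes <- sch$test[sch$test$set_size == 3L, ]
  n <- 51000L
  params <- generative_params(0.6, 0.25, 0.15, sigma = 0.04, p_identify = 1)
  set.seed(4)
  tr <- simulate_trial_responses(threes[rep(1:nrow(threes),
                                            length.out = n), ], params)
  freq <- table(factor(tr$true_component,
                       c("target", "misbind", "guess"))) / n
  truth <- c(0.6, 0.25, 0.15)
  se <- sqrt(truth * (1 - truth) / n)
  expect_true(all(abs(as.numeric(freq) - truth) < 3 * se))
})

test_that("screen truncation leaves target responses nearly unbiased", {
  sch <- make_session_schedule(9)
  interior <- sch$test[!is.na(sch$test$item1_x) &
                         sch$test$target_index == 1L &
                         sch$test$item1_x > 0.1 & sch$test$item1_x < 0.9 &
                         sch$test$item1_y > 0.1 & sch$test$item1_y < 0.9, ]
  params <- generative_params(1, 0, 0, sigma = 0.05, p_identify = 1)
  set.seed(5)
  tr <- simulate_trial_responses(interior[rep(1:nrow(interior),
                                              length.out = 20000L), ], params)
  dx <- tr$response_x - tr$item1_x
  dy <- tr$response_y - tr$item1_y
  expect_lt(abs(mean(dx)), 0.005)
  expect_lt(abs(mean(dy)), 0.005)
})

test_that("latent severity link couples ACE and hippocampal volume", {
  model <- default_covariate_model()
  noiseless <- model
  noiseless$ace_noise_sd <- 0
  noiseless$hv_noise_sd <- 0
  at0 <- latent_severity_link(0, noiseless)
  expect_equal(at0$ace, pmin(model$ace_baseline, 100))
  expect_equal(at0$hv_mm3, model$hv_baseline)
  set.seed(6)
  sev <- stats::rnorm(1000, 1, 1)
  out <- latent_severity_link(sev, model)
  expect_gt(stats::cor(out$ace, out$hv_mm3), 0)
})

test_that("cohorts are reproducible and correctly sized", {
  a <- make_cohort(n_per_group = 3, sessions = 1, seed = 11)
  b <- make_cohort(n_per_group = 3, sessions = 1, seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a$participants), 12L)
  expect_equal(nrow(a$trials), 12L * 120L)
  expect_equal(as.vector(table(a$participants$group)), rep(3L, 4))
  two <- make_cohort(n_per_group = 2, sessions = 2, seed = 12)
  expect_equal(nrow(two$participants), 16L)
  expect_equal(sort(unique(two$participants$session)), c(1L, 2L))
  expect_error(make_cohort(n_per_group = 0), "n_per_group")
})

test_that("group presets produce severity-ordered estimated misbinding", {
  co <- make_cohort(n_per_group = c(EHC = 12, MCI = 12, AD = 12), seed = 21)
  sc <- score_cohort(co$trials, method = "exact")
  m <- merge(co$participants, sc, by = c("participant_id", "session"))
  means <- tapply(m$misbinding, droplevels(m$group), mean)
  expect_lt(means[["EHC"]], means[["MCI"]])
  expect_lt(means[["MCI"]], means[["AD"]])
  # imprecision and identification accuracy follow the same severity order
  impr <- tapply(m$imprecision, droplevels(m$group), mean)
  expect_lt(impr[["EHC"]], impr[["AD"]])
  acc <- tapply(m$identification_accuracy, droplevels(m$group), mean)
  expect_gt(acc[["EHC"]], acc[["AD"]])
})

test_that("AD session drift raises second-session imprecision", {
  co <- make_cohort(n_per_group = c(AD = 25), sessions = 2, seed = 31)
  sc <- score_cohort(co$trials, method = "exact")
  m <- merge(co$participants, sc, by = c("participant_id", "session"))
  s1 <- m[m$session == 1L, ]
  s2 <- m[m$session == 2L, ]
  s2 <- s2[match(s1$participant_id, s2$participant_id), ]
  expect_gt(mean(s2$imprecision), mean(s1$imprecision))
  expect_gt(mean(s2$abs_localization_error),
            mean(s1$abs_localization_error))
})

test_that("cohort CSV round trip preserves the tables", {
  co <- make_cohort(n_per_group = 2, sessions = 1, seed = 41)
  dir <- tempfile()
  write_cohort_csv(co, dir)
  back <- read_cohort_csv(dir)
  expect_equal(back$participants$ace, co$participants$ace)
  expect_equal(back$trials$response_x, co$trials$response_x)
  expect_equal(levels(back$participants$group), levels(co$participants$group))
  unlink(dir, recursive = TRUE)
})

test_that("malformed trial logs are rejected with row locations", {
  co <- make_cohort(n_per_group = 1, sessions = 1, seed = 51)
  bad <- co$trials
  bad$set_size[5] <- 2L
  expect_error(omtkit:::validate_trials(bad), "set_size at row")
  bad <- co$trials
  bad$response_x[3] <- 1.7
  expect_error(omtkit:::validate_trials(bad), "row")
  expect_error(omtkit:::validate_trials(co$trials[, -3]), "lacks column")
})
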