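# Builder for participant-level metric tables with known structure.
metric_table <- function(n_per_group, group_shift = c(0, 0, 0, 0), sd = 1,
                         seed = 1) {
  set.seed(seed)
  groups <- rep(c("EHC", "SCD", "MCI", "AD"), each = n_per_group)
  data.frame(
    participant_id = sprintf("P%03d", seq_along(groups)),
    group = factor(groups, levels = c("EHC", "SCD", "MCI", "AD")),
    metric = stats::rnorm(length(groups),
                          rep(group_shift, each = n_per_group), sd),
    age = stats::rnorm(length(groups), 70, 5),
    gender = sample(c("M", "F"), length(groups), replace = TRUE),
    education = stats::rnorm(length(groups), 14, 2)
  )
}

test_that("Holm adjustment matches the hand-computed step-down", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  p <- c(0.004, 0.3, 0.02, 0.8)
  expect_equal(min(holm_adjust(p)), length(p) * min(p))
  set.seed(1)
  for (i in 1:10) {
    p <- stats::runif(6)
    a <- holm_adjust(p)
    expect_true(all(a >= p))
    expect_true(all(a <= 1))
    expect_true(all(diff(a[order(p)]) >= -1e-12))
  }
})

test_that("two-group ANCOVA without covariates reduces to the t-test", {
  d <- metric_table(15, c(0, 0.8, 0, 0), seed = 2)
  d <- droplevels(d[d$group %in% c("EHC", "SCD"), ])
  res <- ancova_groups(d, "metric", covariates = character(0))
  tt <- stats::t.test(metric ~ group, data = d, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res$p, tt$p.value, tolerance = 1e-8)
  raw_d <- res$pairwise$cohens_d[1]
  expect_gt(abs(raw_d), 0) # sign: EHC - SCD
  expect_equal(sign(raw_d), sign(mean(d$metric[d$group == "EHC"]) -
                                   mean(d$metric[d$group == "SCD"])))
})

test_that("group ANCOVA detects a planted separation and reports eta^2", {
  d <- metric_table(30, c(0, 0.1, 0.8, 1.6), seed = 3)
  res <- ancova_groups(d, "metric")
  expect_lt(res$p, 1e-4)
  expect_true(res$eta_squared > 0 && res$eta_squared < 1)
  expect_equal(nrow(res$pairwise), 6L)
  # Holm p for the largest contrast is the smallest
  extreme <- res$pairwise$group_a == "EHC" & res$pairwise$group_b == "AD"
  expect_equal(min(res$pairwise$p_holm), res$pairwise$p_holm[extreme])
  expect_error(
    ancova_groups(transform(d, age2 = age), "metric",
                  covariates = c("age", "age2")),
    "collinear"
  )
})

test_that("repeated-measures 2x2 ANOVA finds planted factorial effects", {
  set.seed(4)
  n <- 100
  base <- stats::rnorm(n)
  cells <- expand.grid(set_size = c(1L, 3L), delay_s = c(1, 4))
  d <- do.call(rbind, lapply(1:4, function(r) {
    data.frame(participant_id = sprintf("P%03d", 1:n),
               set_size = cells$set_size[r], delay_s = cells$delay_s[r],
               value = base + 0.5 * (cells$set_size[r] == 3L) +
                 stats::rnorm(n, 0, 0.4))
  }))
  res <- factorial_2x2(d)
  expect_equal(res$effect_name, c("set_size", "delay", "interaction"))
  expect_lt(res$p[res$effect_name == "set_size"], 0.001)
  expect_gt(res$p[res$effect_name == "delay"], 0.05)
  # near-constant cells: nothing to detect
  flat <- d
  flat$value <- rep(stats::rnorm(n), 4) + stats::rnorm(nrow(d), 0, 1e-6)
  res_flat <- factorial_2x2(flat)
  expect_true(all(res_flat$eta_squared < 1e-6))
  # delay-only variant for metrics undefined at set size 1
  res_delay <- factorial_2x2(d[d$set_size == 3L, ], factors = "delay")
  expect_equal(res_delay$effect_name, "delay")
})

test_that("eta squared magnitude classes follow the standard cutoffs", {
  expect_equal(omtkit:::eta_magnitude(0.10), "medium")
  expect_equal(omtkit:::eta_magnitude(0.20), "large")
  expect_equal(omtkit:::eta_magnitude(0.02), "small")
  expect_equal(omtkit:::eta_magnitude(0.005), "negligible")
})

test_that("a constant session shift yields a session main effect only", {
  d1 <- metric_table(12, c(0, 0, 0, 0), seed = 5)
  d1$session <- 1L
  d2 <- d1
  d2$session <- 2L
  d2$metric <- d2$metric + 1 + stats::rnorm(nrow(d2), 0, 0.1)
  d <- rbind(d1, d2)
  res <- longitudinal_ancova(d, "metric")
  p <- res$effects$p
  names(p) <- res$effects$effect_name
  expect_lt(p[["session"]], 0.001)
  expect_gt(p[["interaction"]], 0.05)
  expect_error(longitudinal_ancova(d1, "metric"), "two sessions")
})

test_that("decline regression recovers exact and absent relationships", {
  set.seed(6)
  x <- stats::runif(40)
  t0 <- stats::rnorm(40, 90, 3)
  t1 <- t0 - 2 * x # exact linear decline in the metric
  res <- suppressWarnings(predict_decline(x, t0, t1))
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  expect_equal(res$slope, -2, tolerance = 1e-8)
  null <- predict_decline(x, t0, t0 + stats::rnorm(40))
  expect_true(null$r_squared < 0.3)
  expect_error(predict_decline(x[1:2], t0[1:2], t1[1:2]), "at least 3")
})

test_that("dependent-correlation test matches its closed form", {
  eq <- compare_dependent_overlapping_correlations(0.4, 0.4, 0.2, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # independent transcription of the Dunn & Clark style statistic
  r_jk <- 0.6; r_jh <- 0.3; r_kh <- 0.4; n <- 138
  zf <- atanh(c(r_jk, r_jh))
  rm_h <- tanh(mean(zf))
  c_h <- (r_kh * (1 - 2 * rm_h^2) - 0.5 * rm_h^2 *
            (1 - 2 * rm_h^2 - r_kh^2)) / (1 - rm_h^2)^2
  z_ref <- (zf[1] - zf[2]) * sqrt((n - 3) / (2 - 2 * c_h))
  res <- compare_dependent_overlapping_correlations(r_jk, r_jh, r_kh, n)
  expect_equal(res$z, z_ref, tolerance = 1e-6)
  expect_equal(res$method, "hittner_h")
  st <- compare_dependent_overlapping_correlations(r_jk, r_jh, r_kh, n,
                                                   method = "steiger")
  expect_equal(st$method, "steiger_z")
  expect_false(isTRUE(all.equal(st$z, res$z)))
  expect_lt(abs(st$z - res$z), 0.05) # variants agree closely
  expect_error(compare_dependent_overlapping_correlations(1, .3, .2, 50),
               "within")
  expect_error(compare_dependent_overlapping_correlations(.5, .3, .2, 3),
               "exceed 3")
})

test_that("hippocampal-volume regression reports fit and metric effect", {
  d <- metric_table(20, seed = 7)
  d$hv_mm3 <- d$metric # metric reproduces HV exactly
  res <- suppressWarnings(glm_hv(d, "metric"))
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  expect_lt(res$p, 1e-10)
  set.seed(8)
  d$hv_mm3 <- 8000 + 400 * d$metric + stats::rnorm(nrow(d), 0, 200)
  res <- glm_hv(d, "metric")
  expect_gt(res$t, 0)
  expect_true(res$r_squared > 0 && res$r_squared < 1)
})
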