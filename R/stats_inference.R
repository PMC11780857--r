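#' Holm step-down multiple-comparison adjustment
#'
#' Thin, named wrapper over `stats::p.adjust(method = "holm")`: sort the m
#' raw p-values ascending, multiply the i-th by (m - i + 1), enforce
#' monotonicity, cap at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}

cohens_d <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Covariate-adjusted group comparison of one metric
#'
#' Fits the linear model `metric ~ group + age + gender + education`, reports
#' the omnibus group F (Type II sum of squares) with partial eta squared, and
#' all pairwise covariate-adjusted group contrasts (estimated marginal means)
#' with Holm-corrected p-values. Cohen's d for each pair is computed on the
#' raw, covariate-unadjusted metric with a pooled SD.
#'
#' @param data Data frame with the metric column, `group` (factor), `age`,
#'   `gender`, `education`.
#' @param metric Name of the metric column.
#' @param covariates Character vector of covariate columns.
#' @return A list of class `omt_group_comparison`: `metric_name`, `F`, `p`,
#'   `eta_squared` (partial), `n`, and `pairwise` (data frame with
#'   `group_a`, `group_b`, `t`, `p_holm`, `cohens_d`).
#' @export
ancova_groups <- function(data, metric,
                          covariates = c("age", "gender", "education")) {
  keep <- stats::complete.cases(data[, c(metric, "group", covariates)])
  data <- droplevels(data[keep, , drop = FALSE])
  if (nlevels(data$group) < 2L) stop("need at least two groups")
  fml <- stats::reformulate(c("group", covariates), response = metric)
  fit <- stats::lm(fml, data = data)
  a2 <- car::Anova(fit, type = 2)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; collinear terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  ss_group <- a2["group", "Sum Sq"]
  ss_res <- a2["Residuals", "Sum Sq"]
  emm <- emmeans::emmeans(fit, "group")
  prs <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "holm"))
  pair_names <- strsplit(as.character(prs$contrast), " - ")
  pairwise <- data.frame(
    group_a = vapply(pair_names, `[`, "", 1L),
    group_b = vapply(pair_names, `[`, "", 2L),
    t = prs$t.ratio,
    p_holm = prs$p.value,
    cohens_d = NA_real_
  )
  for (i in seq_len(nrow(pairwise))) {
    xa <- data[[metric]][data$group == pairwise$group_a[i]]
    xb <- data[[metric]][data$group == pairwise$group_b[i]]
    pairwise$cohens_d[i] <- cohens_d(xa, xb)
  }
  structure(
    list(
      metric_name = metric,
      F = a2["group", "F value"],
      p = a2["group", "Pr(>F)"],
      eta_squared = ss_group / (ss_group + ss_res),
      n = nrow(data),
      pairwise = pairwise
    ),
    class = "omt_group_comparison"
  )
}

#' @export
print.omt_group_comparison <- function(x, ...) {
  cat(sprintf("%s: F = %.2f, p = %.4g, partial eta^2 = %.3f (n = %d)\n",
              x$metric_name, x$F, x$p, x$eta_squared, x$n))
  print(x$pairwise, digits = 3)
  invisible(x)
}

eta_magnitude <- function(eta2) {
  if (eta2 > 0.14) "large" else if (eta2 > 0.06) "medium"
  else if (eta2 > 0.01) "small" else "negligible"
}

#' Repeated-measures set-size by delay ANOVA
#'
#' Two-way within-participant ANOVA of a per-condition metric over the 2x2
#' design (set size 1/3 by delay 1 s/4 s), with participant as the blocking
#' factor. Effect sizes are classical eta squared (effect SS over total SS,
#' all strata), classed as large (> 0.14), medium (> 0.06), small (> 0.01)
#' or negligible. Metrics defined only at set size 3 (misbinding) are
#' analysed with `factors = "delay"` as a one-way repeated-measures ANOVA.
#'
#' @param cond_data Long data frame: `participant_id`, `set_size`, `delay_s`,
#'   `value`; participants missing any design cell are dropped with a
#'   warning.
#' @param factors `"both"` or `"delay"`.
#' @return Data frame with one row per effect: `effect_name`, `F`, `p`,
#'   `eta_squared`, `magnitude_class`.
#' @export
factorial_2x2 <- function(cond_data, factors = c("both", "delay")) {
  factors <- match.arg(factors)
  cond_data <- cond_data[!is.na(cond_data$value), , drop = FALSE]
  cells_needed <- if (factors == "both") 4L else 2L
  counts <- table(cond_data$participant_id)
  complete <- names(counts)[counts == cells_needed]
  if (length(complete) < length(counts)) {
    warning(length(counts) - length(complete),
            " participant(s) dropped for missing design cells")
  }
  d <- cond_data[cond_data$participant_id %in% complete, , drop = FALSE]
  d$participant_id <- factor(d$participant_id)
  d$ss <- factor(d$set_size)
  d$delay <- factor(d$delay_s)
  if (factors == "both") {
    fit <- stats::aov(value ~ ss * delay + Error(participant_id),
                      data = d)
    effects <- c(ss = "set_size", delay = "delay", `ss:delay` = "interaction")
  } else {
    fit <- stats::aov(value ~ delay + Error(participant_id), data = d)
    effects <- c(delay = "delay")
  }
  sm <- summary(fit)
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  between <- as.data.frame(sm[["Error: participant_id"]][[1]])
  ss_total <- sum(within[, "Sum Sq"]) + sum(between[, "Sum Sq"])
  rn <- trimws(rownames(within))
  out <- data.frame(effect_name = unname(effects), F = NA_real_,
                    p = NA_real_, eta_squared = NA_real_,
                    magnitude_class = NA_character_)
  for (i in seq_along(effects)) {
    row <- match(names(effects)[i], rn)
    out$F[i] <- within[row, "F value"]
    out$p[i] <- within[row, "Pr(>F)"]
    out$eta_squared[i] <- within[row, "Sum Sq"] / ss_total
    out$magnitude_class[i] <- eta_magnitude(out$eta_squared[i])
  }
  out
}

#' Longitudinal group-by-session analysis of one metric
#'
#' Mixed ANOVA/ANCOVA with group as the between-participant factor, session
#' as the within-participant factor and age, gender and education as
#' between-participant covariates (fitted before group, sequential sums of
#' squares). Post hoc, each group's session-2 minus session-1 change is
#' tested with a paired t-test; the per-group p-values are Holm-corrected.
#'
#' @param data Data frame with one row per participant-session: the metric
#'   column, `participant_id`, `group`, `session` (1/2), covariates.
#' @param metric Name of the metric column.
#' @param covariates Covariate columns.
#' @return List: `effects` (data frame with `effect_name` in
#'   `group, session, interaction`, `F`, `p`), and `session_posthoc` (data
#'   frame with per-group `t`, `p`, `p_holm`, `mean_change`).
#' @export
longitudinal_ancova <- function(data, metric,
                                covariates = c("age", "gender", "education")) {
  if (length(unique(data$session)) < 2L) {
    stop("longitudinal analysis requires two sessions")
  }
  keep_ids <- names(which(table(data$participant_id) == 2L))
  d <- data[data$participant_id %in% keep_ids, , drop = FALSE]
  d <- d[stats::complete.cases(d[, c(metric, "group", covariates)]), ,
         drop = FALSE]
  keep_ids <- names(which(table(d$participant_id) == 2L))
  d <- droplevels(d[d$participant_id %in% keep_ids, , drop = FALSE])
  d$participant_id <- factor(d$participant_id)
  d$session_f <- factor(d$session)
  fml <- stats::as.formula(paste(
    metric, "~", paste(covariates, collapse = " + "),
    "+ group * session_f + Error(participant_id)"
  ))
  fit <- stats::aov(fml, data = d)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: participant_id"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  rb <- trimws(rownames(between))
  rw <- trimws(rownames(within))
  effects <- data.frame(
    effect_name = c("group", "session", "interaction"),
    F = c(between[match("group", rb), "F value"],
          within[match("session_f", rw), "F value"],
          within[match("group:session_f", rw), "F value"]),
    p = c(between[match("group", rb), "Pr(>F)"],
          within[match("session_f", rw), "Pr(>F)"],
          within[match("group:session_f", rw), "Pr(>F)"])
  )
  groups <- levels(d$group)
  ph <- data.frame(group = groups, mean_change = NA_real_, t = NA_real_,
                   p = NA_real_)
  for (i in seq_along(groups)) {
    sub <- d[d$group == groups[i], , drop = FALSE]
    s1 <- sub[sub$session == 1L, ]
    s2 <- sub[sub$session == 2L, ]
    s2 <- s2[match(s1$participant_id, s2$participant_id), ]
    delta <- s2[[metric]] - s1[[metric]]
    tt <- stats::t.test(delta)
    ph$mean_change[i] <- mean(delta)
    ph$t[i] <- unname(tt$statistic)
    ph$p[i] <- tt$p.value
  }
  ph$p_holm <- holm_adjust(ph$p)
  list(effects = effects, session_posthoc = ph)
}

#' Predict one-year cognitive decline from a baseline metric
#'
#' Regresses the ACE change (follow-up minus baseline; negative = decline)
#' on a baseline task metric.
#'
#' @param baseline_metric Numeric vector of baseline metric values.
#' @param ace_t0,ace_t1 Baseline and follow-up ACE scores, same order.
#' @param predictor_name Label carried into the result.
#' @return List: `predictor_name`, `t`, `p`, `r_squared`, `n`, `slope`.
#' @export
predict_decline <- function(baseline_metric, ace_t0, ace_t1,
                            predictor_name = "metric") {
  keep <- stats::complete.cases(baseline_metric, ace_t0, ace_t1)
  x <- baseline_metric[keep]
  delta <- ace_t1[keep] - ace_t0[keep]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  fit <- stats::lm(delta ~ x)
  sm <- summary(fit)
  list(predictor_name = predictor_name,
       t = sm$coefficients["x", "t value"],
       p = sm$coefficients["x", "Pr(>|t|)"],
       r_squared = sm$r.squared,
       slope = stats::coef(fit)[["x"]],
       n = length(x))
}

#' Compare two dependent overlapping correlations
#'
#' Tests H0: rho_jk = rho_jh for two correlations sharing the variable j and
#' measured on the same sample, given the correlation r_kh between the two
#' non-shared variables. The default is the Hittner, May and Silver
#' modification of Dunn and Clark's z, which plugs the backtransformed
#' average Fisher z of the two correlations into the covariance term;
#' Steiger's variant (plain average correlation) is also available. The
#' statistic is
#' `z = (z_jk - z_jh) * sqrt((n - 3) / (2 - 2 c))` with `c` the correlation
#' between the two Fisher-transformed sample correlations.
#'
#' @param r_jk,r_jh The two overlapping correlations (shared variable j).
#' @param r_kh Correlation between the non-shared variables.
#' @param n Sample size (> 3).
#' @param method `"hittner"` (default) or `"steiger"`.
#' @return List of class `omt_cocor`: the inputs, `z`, two-sided `p`,
#'   `method`.
#' @export
compare_dependent_overlapping_correlations <- function(r_jk, r_jh, r_kh, n,
                                                       method = c("hittner",
                                                                  "steiger")) {
  method <- match.arg(method)
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1)) {
    stop("correlations must lie strictly within (-1, 1)")
  }
  if (n <= 3L) stop("n must exceed 3")
  z_jk <- atanh(r_jk)
  z_jh <- atanh(r_jh)
  rm <- if (method == "hittner") tanh((z_jk + z_jh) / 2) else (r_jk + r_jh) / 2
  cov_term <- (r_kh * (1 - 2 * rm^2) -
                 0.5 * rm^2 * (1 - 2 * rm^2 - r_kh^2)) / (1 - rm^2)^2
  z <- (z_jk - z_jh) * sqrt((n - 3) / (2 - 2 * cov_term))
  structure(
    list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n, z = z,
         p = 2 * stats::pnorm(-abs(z)),
         method = if (method == "hittner") "hittner_h" else "steiger_z"),
    class = "omt_cocor"
  )
}

#' @export
print.omt_cocor <- function(x, ...) {
  cat(sprintf("%s: z = %.4f, p = %.4g (r_jk = %.3f, r_jh = %.3f, n = %d)\n",
              x$method, x$z, x$p, x$r_jk, x$r_jh, x$n))
  invisible(x)
}

#' Hippocampal-volume regression on a task metric
#'
#' Linear model `hv ~ metric + age + gender + education`; reports the
#' metric's t statistic and p-value together with the overall model fit
#' (R squared).
#'
#' @param data Data frame with `hv_mm3`, the metric column and covariates.
#' @param metric Name of the metric column.
#' @param covariates Covariate columns.
#' @return List: `metric_name`, `t`, `p`, `r_squared`, `n`, and the
#'   correlation sign-carrying `estimate`.
#' @export
glm_hv <- function(data, metric,
                   covariates = c("age", "gender", "education")) {
  keep <- stats::complete.cases(data[, c("hv_mm3", metric, covariates)])
  d <- data[keep, , drop = FALSE]
  fml <- stats::reformulate(c(metric, covariates), response = "hv_mm3")
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; collinear terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  sm <- summary(fit)
  list(metric_name = metric,
       estimate = sm$coefficients[metric, "Estimate"],
       t = sm$coefficients[metric, "t value"],
       p = sm$coefficients[metric, "Pr(>|t|)"],
       r_squared = sm$r.squared,
       n = nrow(d))
}
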