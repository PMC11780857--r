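#' AUC and DeLong variance machinery
#'
#' `roc_auc` computes the area under the ROC curve of a score vector as the
#' normalized Mann-Whitney statistic (ties counted one half).
#'
#' @param scores Numeric scores; larger means more likely positive.
#' @param labels Logical or 0/1 vector marking positives.
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg)) stop("need both classes to compute AUC")
  mean(placement_values(pos, neg))
}

# DeLong placement values of positives against negatives: for each positive
# score, the fraction of negatives it beats (ties half).
placement_values <- function(pos, neg) {
  vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), numeric(1))
}

delong_components <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  v10 <- placement_values(pos, neg)          # one per positive
  v01 <- 1 - placement_values(neg, pos)      # one per negative
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' Compare two correlated ROC curves (DeLong's test)
#'
#' Nonparametric comparison of the AUCs of two score vectors on the same
#' cases, using DeLong's placement-value covariance for paired curves. With
#' `paired = FALSE` the variance is the sum of the two independent DeLong
#' variances.
#'
#' @param scores_a,scores_b Numeric score vectors (same cases when paired).
#' @param labels Logical or 0/1 vector of class labels, shared by both.
#' @param paired Whether the scores were computed on the same cases.
#' @return List of class `omt_delong`: `auc_a`, `auc_b`, `Z`, `p` (two-sided
#'   normal), `se_diff`, `paired`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, paired = TRUE) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  if (paired && length(scores_a) != length(scores_b)) {
    stop("paired comparison requires identical case sets")
  }
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- sum(labels)
  n <- sum(!labels)
  var_a <- stats::var(ca$v10) / m + stats::var(ca$v01) / n
  var_b <- stats::var(cb$v10) / m + stats::var(cb$v01) / n
  cov_ab <- if (paired) {
    stats::cov(ca$v10, cb$v10) / m + stats::cov(ca$v01, cb$v01) / n
  } else 0
  se <- sqrt(max(var_a + var_b - 2 * cov_ab, 0))
  z <- if (se == 0) 0 else (ca$auc - cb$auc) / se
  structure(
    list(auc_a = ca$auc, auc_b = cb$auc, Z = z,
         p = if (se == 0) 1 else 2 * stats::pnorm(-abs(z)),
         se_diff = se, paired = paired),
    class = "omt_delong"
  )
}

#' @export
print.omt_delong <- function(x, ...) {
  cat(sprintf("DeLong %s test: AUC %.3f vs %.3f, Z = %.3f, p = %.4g\n",
              if (x$paired) "paired" else "unpaired",
              x$auc_a, x$auc_b, x$Z, x$p))
  invisible(x)
}
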