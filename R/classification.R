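#' Feature columns for the two competing classification models
#'
#' The task model uses the eight digital metrics plus age, gender and
#' education; the competing standard-test model uses the ACE score plus the
#' same demographics.
#'
#' @param which `"omt"` (eight digital metrics) or `"ace"`.
#' @return Character vector of column names; gender must be provided as the
#'   numeric indicator `gender_num`.
#' @export
feature_set_columns <- function(which = c("omt", "ace")) {
  which <- match.arg(which)
  demo <- c("age", "gender_num", "education")
  if (which == "omt") {
    c("identification_accuracy", "abs_localization_error",
      "identification_time_s", "localization_time_s",
      "target_detection", "misbinding", "guessing", "imprecision", demo)
  } else {
    c("ace", demo)
  }
}

# Ensure the numeric gender indicator exists.
add_gender_indicator <- function(data) {
  if (is.null(data$gender_num)) data$gender_num <- as.numeric(data$gender == "F")
  data
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

balanced_class_weights <- function(y) {
  tab <- table(y)
  w <- as.numeric(sum(tab) / (length(tab) * tab))
  stats::setNames(w, names(tab))
}

# Decision score of a binary linear SVM oriented so larger favours `positive`.
ovr_scores <- function(xtr, ytr_bin, xte, cost) {
  fit <- e1071::svm(x = xtr, y = ytr_bin, kernel = "linear", cost = cost,
                    scale = FALSE, class.weights = balanced_class_weights(ytr_bin))
  dv <- attr(stats::predict(fit, xte, decision.values = TRUE),
             "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (first == "pos") dv[, 1] else -dv[, 1]
}

#' Cross-validated linear SVM group classification
#'
#' Stratified k-fold cross-validation of a linear support vector machine.
#' Within each training fold the features are standardized (centre/SD from
#' the training fold only, then applied to the held-out fold) and balanced
#' class weights are used. The multiclass label is predicted with the usual
#' one-vs-one voting; per-class ROC scores come from one-vs-rest linear SVM
#' decision values, so each class has an out-of-fold score on every case.
#'
#' @param data Data frame with the feature columns and a factor label
#'   column.
#' @param features Character vector of feature columns (see
#'   [feature_set_columns()]).
#' @param label_col Name of the class column (factor).
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @param cost SVM regularization parameter C.
#' @return List of class `omt_classifier_eval`: `auc` (named per class),
#'   `accuracy`, `scores` (cases x classes out-of-fold decision values),
#'   `predicted`, `labels`, `fold`.
#' @export
fit_eval_classifier <- function(data, features, label_col = "group",
                                folds = 5L, seed = 1L, cost = 1) {
  data <- add_gender_indicator(data)
  y <- droplevels(factor(data[[label_col]]))
  if (nlevels(y) < 2L) stop("need at least two classes")
  x <- as.matrix(data[, features, drop = FALSE])
  if (anyNA(x)) {
    keep <- stats::complete.cases(x)
    x <- x[keep, , drop = FALSE]
    y <- droplevels(y[keep])
  }
  if (min(table(y)) < folds) {
    stop("smallest class has fewer members than folds; reduce folds")
  }
  set.seed(as.integer(seed))
  fold <- stratified_folds(y, folds)
  classes <- levels(y)
  scores <- matrix(NA_real_, nrow(x), length(classes),
                   dimnames = list(NULL, classes))
  predicted <- factor(rep(NA_character_, nrow(x)), levels = classes)
  for (f in seq_len(folds)) {
    tr <- fold != f
    te <- !tr
    mu <- colMeans(x[tr, , drop = FALSE])
    sd <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sd[sd == 0] <- 1
    xtr <- scale(x[tr, , drop = FALSE], mu, sd)
    xte <- scale(x[te, , drop = FALSE], mu, sd)
    ytr <- y[tr]
    multi <- e1071::svm(x = xtr, y = ytr, kernel = "linear", cost = cost,
                        scale = FALSE,
                        class.weights = balanced_class_weights(ytr))
    predicted[te] <- stats::predict(multi, xte)
    for (cl in classes) {
      ybin <- factor(ifelse(ytr == cl, "pos", "neg"),
                     levels = c("pos", "neg"))
      scores[te, cl] <- ovr_scores(xtr, ybin, xte, cost)
    }
  }
  auc <- vapply(classes, function(cl) roc_auc(scores[, cl], y == cl),
                numeric(1))
  structure(
    list(auc = auc, accuracy = mean(predicted == y), scores = scores,
         predicted = predicted, labels = y, fold = fold),
    class = "omt_classifier_eval"
  )
}

#' @export
print.omt_classifier_eval <- function(x, ...) {
  cat(sprintf("linear SVM, %d-fold CV: accuracy %.3f\n",
              max(x$fold), x$accuracy))
  cat("  per-class AUC:",
      paste(sprintf("%s=%.3f", names(x$auc), x$auc), collapse = " "), "\n")
  invisible(x)
}

#' Pairwise group classification: digital metrics vs ACE
#'
#' For each requested group pair, fits cross-validated binary linear SVMs
#' under the digital-metric feature set and the ACE feature set, scores each
#' case out of fold, and compares the two correlated ROC curves with the
#' paired DeLong test. Scores are oriented towards the second (more
#' impaired) group of each pair.
#'
#' @param data Participant-level table with the eight metrics, `ace`,
#'   demographics and `group`.
#' @param pairs List of length-2 character vectors of group names.
#' @param folds,seed,cost As in [fit_eval_classifier()].
#' @return Data frame: `group_a`, `group_b`, `auc_omt`, `auc_ace`, `Z`, `p`
#'   (DeLong comparison of the two models), `n`.
#' @export
pairwise_suite <- function(data,
                           pairs = list(c("EHC", "SCD"), c("SCD", "MCI"),
                                        c("MCI", "AD")),
                           folds = 5L, seed = 1L, cost = 1) {
  data <- add_gender_indicator(data)
  out <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    sub <- droplevels(data[data$group %in% pr, , drop = FALSE])
    sub$group <- factor(sub$group, levels = pr)
    ev_omt <- fit_eval_classifier(sub, feature_set_columns("omt"),
                                  folds = folds, seed = seed, cost = cost)
    ev_ace <- fit_eval_classifier(sub, feature_set_columns("ace"),
                                  folds = folds, seed = seed + 1L,
                                  cost = cost)
    positive <- pr[2]
    labels <- ev_omt$labels == positive
    cmp <- delong_compare(ev_omt$scores[, positive],
                          ev_ace$scores[, positive], labels, paired = TRUE)
    out[[i]] <- data.frame(
      group_a = pr[1], group_b = pr[2],
      auc_omt = cmp$auc_a, auc_ace = cmp$auc_b,
      Z = cmp$Z, p = cmp$p, n = nrow(sub)
    )
  }
  do.call(rbind, out)
}
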