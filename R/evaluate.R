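# Discrimination metrics (ROC/AUC with DeLong or bootstrap intervals,
# Harrell's concordance) and an event-stratified cross-validation harness
# into which any survival learner satisfying the fit/predict-risk contract
# can be plugged.

#' ROC curve, AUC and confidence interval
#'
#' AUC via the rank (Mann-Whitney) formulation with the usual 1/2 credit
#' for ties, as computed by [pROC::roc()]; the 95% CI by DeLong's method
#' (default) or a seeded bootstrap.
#'
#' @param scores Numeric risk scores (higher = riskier).
#' @param labels Binary event labels; both classes must be present.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n Bootstrap resamples when `ci_method = "bootstrap"`.
#' @return List with `auc`, `ci` (length 2), and `roc` (data frame of
#'   `threshold`, `sensitivity`, `specificity`).
#' @export
roc_auc_ci <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                       boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- as.integer(labels[ok])
  if (length(unique(labels)) < 2) stop("both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  ci <- if (ci_method == "bootstrap")
    pROC::ci.auc(r, method = "bootstrap", boot.n = boot_n)
  else pROC::ci.auc(r, method = "delong")
  list(auc = as.numeric(pROC::auc(r)),
       ci = c(as.numeric(ci[1]), as.numeric(ci[3])),
       roc = data.frame(threshold = r$thresholds,
                        sensitivity = r$sensitivities,
                        specificity = r$specificities))
}

#' Harrell's concordance index
#'
#' Probability that, of a comparable patient pair, the one with the higher
#' score fails first. Comparable pairs: both events with distinct times, or
#' an event paired with a patient censored at or after the event time.
#' Score ties get 1/2 credit. Computed by [survival::concordance()].
#'
#' @param scores Numeric risk scores (higher = riskier).
#' @param times Follow-up times.
#' @param events Event indicators (0/1).
#' @return Concordance in `[0, 1]`.
#' @export
c_index <- function(scores, times, events) {
  if (sum(events) < 1) stop("no comparable pairs: no events")
  fit <- survival::concordance(survival::Surv(times, events) ~ scores,
                               reverse = TRUE)
  as.numeric(fit$concordance)
}

#' Full discrimination evaluation of a score
#'
#' Combines [roc_auc_ci()], [c_index()], and precision/recall at a stated
#' threshold (default: the median score among complete cases; patients at
#' or above the threshold are called positive).
#'
#' @param scores Numeric risk scores.
#' @param outcomes Data frame with `time_days` and `event` (excluded rows
#'   dropped if flagged).
#' @param threshold Classification threshold for precision/recall;
#'   `NULL` for the median score.
#' @param ci_method,boot_n Passed to [roc_auc_ci()].
#' @return Object of class `score_evaluation`.
#' @export
evaluate_score <- function(scores, outcomes, threshold = NULL,
                           ci_method = "delong", boot_n = 2000) {
  if (!is.null(outcomes$excluded)) {
    keep <- !outcomes$excluded
    outcomes <- outcomes[keep, , drop = FALSE]
    scores <- scores[keep]
  }
  ok <- !is.na(scores)
  scores <- scores[ok]
  outcomes <- outcomes[ok, , drop = FALSE]
  rr <- roc_auc_ci(scores, outcomes$event, ci_method = ci_method, boot_n = boot_n)
  ci <- c_index(scores, outcomes$time_days, outcomes$event)
  if (is.null(threshold)) threshold <- stats::median(scores)
  called <- scores >= threshold
  tp <- sum(called & outcomes$event == 1)
  precision <- if (any(called)) tp / sum(called) else NA_real_
  recall <- tp / sum(outcomes$event == 1)
  structure(list(auc = rr$auc, auc_ci = rr$ci, roc = rr$roc, c_index = ci,
                 threshold = threshold, precision = precision, recall = recall,
                 n = nrow(outcomes), n_events = sum(outcomes$event)),
            class = "score_evaluation")
}

#' @export
print.score_evaluation <- function(x, ...) {
  cat(sprintf("Score evaluation (n = %d, events = %d)\n", x$n, x$n_events))
  cat(sprintf("  AUC      %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  C-index  %.3f\n", x$c_index))
  cat(sprintf("  at threshold %.3g: precision %.3f, recall %.3f\n",
              x$threshold, x$precision, x$recall))
  invisible(x)
}

# Event-stratified fold assignment; returns an integer vector in 1..k.
stratified_folds <- function(event, k, seed) {
  set.seed(seed)
  fold <- integer(length(event))
  for (g in unique(event)) {
    idx <- which(event == g)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated evaluation of a survival learner
#'
#' Event-stratified k-fold cross-validation. The learner is any list with
#' `fit(data) -> model` and `predict_risk(model, data) -> numeric scores`
#' (higher = riskier), so fitted risk scores, plain Cox models or
#' third-party survival forests can be benchmarked on the same folds.
#'
#' @param data Cohort data frame containing `time_days` and `event` plus
#'   whatever columns the learner uses.
#' @param learner List with functions `fit` and `predict_risk`.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment (results are reproducible given
#'   the seed).
#' @param threshold Passed to [evaluate_score()].
#' @return List with `folds` (per-fold metric data frame) and `pooled`
#'   (mean over folds of AUC, C-index, precision, recall).
#' @export
cv_evaluate <- function(data, learner, k = 5, seed = 1, threshold = NULL) {
  stopifnot(is.function(learner$fit), is.function(learner$predict_risk))
  if (!is.null(data$excluded)) data <- data[!data$excluded, , drop = FALSE]
  fold <- stratified_folds(data$event, k, seed)
  if (any(tapply(data$event, fold, sum) == 0)) {
    fold <- stratified_folds(data$event, k, seed + 1L)  # one re-randomization
    if (any(tapply(data$event, fold, sum) == 0))
      stop("a fold has no events even after re-randomization")
  }
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    model <- learner$fit(train)
    risk <- learner$predict_risk(model, test)
    ev <- evaluate_score(risk, test, threshold = threshold)
    rows[[f]] <- data.frame(fold = f, n = ev$n, n_events = ev$n_events,
                            auc = ev$auc, c_index = ev$c_index,
                            precision = ev$precision, recall = ev$recall)
  }
  folds <- do.call(rbind, rows)
  pooled <- colMeans(folds[, c("auc", "c_index", "precision", "recall")])
  list(folds = folds, pooled = pooled, fold_assignment = fold)
}
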