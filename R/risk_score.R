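# The central model-fitting interface: formula + data in, a fitted
# point-based risk score out, with the usual accessor methods.

#' Fit a point-based survival risk score
#'
#' Runs the full score-construction procedure on a cohort: univariate Cox
#' screening of every candidate at `alpha_screen` (default 0.10), a joint
#' Cox model on the survivors with one pruning pass at `alpha_select`
#' (default 0.05) and a single refit, decile hazard-ratio profiling of the
#' designated continuous exposures with J/U-shape detection and cut-off
#' derivation, Youden dichotomization of the remaining continuous
#' predictors, a final indicator-coded Cox refit whose hazard ratios feed
#' the point band rule (HR in [0.67, 1.5] scores 1 point, otherwise 2), and
#' in-sample ROC evaluation of the resulting integer score.
#'
#' @param formula Model formula `survival::Surv(time, event) ~ cand1 + ...`;
#'   the right-hand side lists the candidate predictors (numeric or 0/1
#'   binary columns of `data`).
#' @param data Cohort data frame; one row per patient. Rows flagged in an
#'   `excluded` column are dropped.
#' @param profile_vars Character vector of continuous candidates to profile
#'   for a J/U-shaped hazard relationship (e.g. mean HbA1c, HDL-C, total
#'   cholesterol).
#' @param alpha_screen Univariate screening threshold.
#' @param alpha_select Significance threshold in the joint model.
#' @param outcome_name Label for the score (e.g. `"AMI"`).
#' @return Object of class `risk_score` with components `spec`
#'   (the [build_score_spec()] result), `screen`, `joint`, `refit`,
#'   `indicator_fit`, `profiles`, `scores` (in-sample), `evaluation`
#'   (see [evaluate_score()]), `n`, `n_events`, `call`.
#' @seealso [predict.risk_score()], [plot.risk_score()],
#'   [summary.risk_score()]
#' @export
risk_score <- function(formula, data, profile_vars = character(),
                       alpha_screen = 0.10, alpha_select = 0.05,
                       outcome_name = "event") {
  cl <- match.call()
  if (!is.null(data$excluded)) data <- data[!data$excluded, , drop = FALSE]
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y))
    stop("the formula response must be a survival::Surv(time, event) object")
  outcomes <- data.frame(time_days = unname(y[, 1]), event = unname(y[, 2]))
  cand_names <- attr(stats::terms(formula, data = data), "term.labels")
  missing_cand <- setdiff(cand_names, names(data))
  if (length(missing_cand))
    stop("candidate(s) not found in data: ", paste(missing_cand, collapse = ", "))
  candidates <- data[, cand_names, drop = FALSE]
  if (!all(profile_vars %in% cand_names))
    stop("profile_vars must be a subset of the candidate predictors")

  screened <- univariate_screen(outcomes, candidates, alpha = alpha_screen)
  refit <- multivariate_refit(outcomes, candidates, screened, alpha = alpha_select)

  profiles <- list()
  for (nm in intersect(profile_vars, refit$term))
    profiles[[nm]] <- decile_hr_profile(outcomes, candidates[[nm]], variable = nm)

  spec <- build_score_spec(refit, profiles, candidates, outcomes,
                           outcome_name = outcome_name)
  scores <- apply_score(spec, candidates)
  evaluation <- if (length(spec$components) && sum(outcomes$event) > 0 &&
                      any(outcomes$event == 0) && length(unique(stats::na.omit(scores))) > 1)
    evaluate_score(scores, outcomes) else NULL

  structure(list(
    call = cl, spec = spec,
    screen = attr(screened, "results"), screened = as.character(screened),
    joint = attr(refit, "joint"), refit = refit,
    indicator_fit = attr(spec, "indicator_fit"),
    profiles = profiles, scores = scores, evaluation = evaluation,
    n = nrow(outcomes), n_events = sum(outcomes$event)
  ), class = "risk_score")
}

#' @export
print.risk_score <- function(x, ...) {
  cat("Call: ")
  print(x$call)
  cat(sprintf("n = %d patients, %d events\n\n", x$n, x$n_events))
  print(x$spec)
  if (!is.null(x$evaluation))
    cat(sprintf("\nIn-sample AUC %.3f (95%% CI %.3f-%.3f), C-index %.3f\n",
                x$evaluation$auc, x$evaluation$auc_ci[1], x$evaluation$auc_ci[2],
                x$evaluation$c_index))
  invisible(x)
}

#' Summarize a fitted risk score
#'
#' @param object A `risk_score`.
#' @param ... Unused.
#' @return Object of class `summary.risk_score` carrying the screening,
#'   joint, refitted and indicator-coded model tables, the shape profiles
#'   and the evaluation.
#' @export
summary.risk_score <- function(object, ...) {
  structure(list(call = object$call, n = object$n, n_events = object$n_events,
                 screen = object$screen, screened = object$screened,
                 joint = object$joint, refit = object$refit,
                 indicator_fit = object$indicator_fit,
                 profiles = object$profiles, spec = object$spec,
                 evaluation = object$evaluation),
            class = "summary.risk_score")
}

#' @export
print.summary.risk_score <- function(x, ...) {
  cat("Point-based risk score fit\n==========================\n")
  cat(sprintf("n = %d, events = %d\n\n", x$n, x$n_events))
  cat("Univariate screen (retained: ",
      if (length(x$screened)) paste(x$screened, collapse = ", ") else "none",
      ")\n", sep = "")
  tab <- x$screen
  tab$hr <- round(tab$hr, 3); tab$lower <- round(tab$lower, 3)
  tab$upper <- round(tab$upper, 3); tab$p <- signif(tab$p, 3)
  print(tab[, c("term", "hr", "lower", "upper", "p")], row.names = FALSE)
  cat("\nRefitted multivariate model\n")
  print(x$refit)
  cat("\nIndicator-coded refit (hazard ratios feeding the point rule)\n")
  print(x$indicator_fit)
  for (pr in x$profiles) {
    cat("\n")
    print(pr)
  }
  cat("\n")
  print(x$spec)
  if (!is.null(x$evaluation)) {
    cat("\n")
    print(x$evaluation)
  }
  invisible(x)
}

#' @export
coef.risk_score <- function(object, ...) {
  fit <- object$indicator_fit
  stats::setNames(fit$coef, fit$term)
}

#' Score new patients with a fitted risk score
#'
#' @param object A `risk_score`.
#' @param newdata Data frame of patients; defaults to the in-sample scores.
#' @param missing_policy See [apply_score()].
#' @param ... Unused.
#' @return Integer score per patient.
#' @export
predict.risk_score <- function(object, newdata = NULL,
                               missing_policy = c("propagate_missing", "score_as_zero"),
                               ...) {
  if (is.null(newdata)) return(object$scores)
  apply_score(object$spec, newdata, missing_policy = match.arg(missing_policy))
}

#' Plot the decile profiles (or ROC curve) of a fitted risk score
#'
#' Plots each stored decile hazard-ratio profile; when the fit has no
#' profiled variable, plots the in-sample ROC curve instead.
#'
#' @param x A `risk_score`.
#' @param ... Passed on to the underlying plot.
#' @export
plot.risk_score <- function(x, ...) {
  if (length(x$profiles)) {
    for (pr in x$profiles) plot(pr, ...)
  } else if (!is.null(x$evaluation)) {
    roc <- x$evaluation$roc
    graphics::plot(1 - roc$specificity, roc$sensitivity, type = "s",
                   xlab = "1 - specificity", ylab = "sensitivity", ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    stop("nothing to plot: empty score")
  }
  invisible(x)
}

#' @export
residuals.risk_score <- function(object, type = "martingale", ...) {
  fit <- attr(object$indicator_fit, "model")
  if (is.null(fit)) stop("no fitted Cox model stored (empty score?)")
  stats::residuals(fit, type = type, ...)
}
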