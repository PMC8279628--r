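# Proportional-hazards fitting and the two-stage predictor selection:
# univariate screen at P < 0.10, joint fit, drop non-significant terms,
# single refit on the survivors (the refitted HRs feed the point rule).

#' Fit a Cox proportional-hazards model
#'
#' Wraps [survival::coxph()] with Breslow tie handling and complete-case
#' covariate handling: rows with any missing covariate are dropped and the
#' dropped count reported. Wald 95% confidence intervals and p-values are
#' returned per covariate.
#'
#' @param outcomes Data frame with `time_days` and `event` (excluded rows,
#'   if an `excluded` column is present, are dropped first).
#' @param covariates Data frame (or matrix) of numeric covariates, aligned
#'   row-wise with `outcomes`.
#' @return Object of class `cox_fit`: a per-covariate table
#'   (`term`, `coef`, `hr`, `lower`, `upper`, `se`, `p`) with attributes
#'   `n_used`, `n_events`, `n_dropped`, `loglik`, `loglik_null`,
#'   `converged`, and the underlying `coxph` fit in `attr(, "model")`.
#' @export
fit_cox <- function(outcomes, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == nrow(outcomes))
  if (!is.null(outcomes$excluded)) {
    keep <- !outcomes$excluded
    outcomes <- outcomes[keep, , drop = FALSE]
    covariates <- covariates[keep, , drop = FALSE]
  }
  cc <- stats::complete.cases(covariates)
  n_dropped <- sum(!cc)
  outcomes <- outcomes[cc, , drop = FALSE]
  covariates <- covariates[cc, , drop = FALSE]
  if (sum(outcomes$event) < 1) stop("no events in the data")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (!is.numeric(v) && !is.logical(v))
      stop("covariate '", nm, "' is not numeric")
    if (length(unique(v)) < 2L)
      stop("degenerate covariate (constant on complete cases): ", nm)
  }
  dat <- cbind(data.frame(.time = outcomes$time_days, .event = outcomes$event),
               covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  s <- summary(fit)
  co <- s$coefficients
  tab <- data.frame(
    term = names(covariates),
    coef = unname(co[, "coef"]),
    hr = unname(exp(co[, "coef"])),
    lower = unname(exp(co[, "coef"] - 1.96 * co[, "se(coef)"])),
    upper = unname(exp(co[, "coef"] + 1.96 * co[, "se(coef)"])),
    se = unname(co[, "se(coef)"]),
    p = unname(co[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("cox_fit", "data.frame"),
            n_used = fit$n, n_events = fit$nevent, n_dropped = n_dropped,
            loglik = fit$loglik[2], loglik_null = fit$loglik[1],
            converged = is.null(fit$info) || fit$iter < 50,
            model = fit)
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("Cox proportional-hazards fit (Breslow ties)\n")
  cat(sprintf("  n = %d, events = %d, rows dropped (missing covariates) = %d\n",
              attr(x, "n_used"), attr(x, "n_events"), attr(x, "n_dropped")))
  tab <- as.data.frame(x)
  tab$coef <- round(tab$coef, digits)
  tab$hr <- round(tab$hr, digits)
  tab$lower <- round(tab$lower, digits)
  tab$upper <- round(tab$upper, digits)
  tab$p <- signif(tab$p, digits)
  tab$se <- NULL
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Univariate screen of candidate predictors
#'
#' Fits one single-covariate Cox model per candidate and retains, in input
#' order, those with Wald p below `alpha` (default 0.10). Degenerate
#' candidates (constant, or otherwise unfittable) are skipped with a
#' warning rather than failing the screen.
#'
#' @param outcomes Outcome data frame (see [fit_cox()]).
#' @param covariates Data frame of candidate covariates.
#' @param alpha Retention threshold on the univariate Wald p-value.
#' @return Character vector of retained candidate names; the full
#'   per-candidate results table is attached as `attr(, "results")`.
#' @export
univariate_screen <- function(outcomes, covariates, alpha = 0.10) {
  covariates <- as.data.frame(covariates)
  if (!ncol(covariates)) stop("no candidate covariates supplied")
  rows <- list()
  for (nm in names(covariates)) {
    fit <- tryCatch(fit_cox(outcomes, covariates[, nm, drop = FALSE]),
                    error = function(e) {
                      warning("skipping candidate '", nm, "': ", conditionMessage(e),
                              call. = FALSE)
                      NULL
                    })
    if (!is.null(fit)) rows[[nm]] <- as.data.frame(fit)
  }
  if (!length(rows)) stop("no candidate could be fitted")
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  retained <- results$term[results$p < alpha]
  structure(retained, results = results)
}

#' Multivariate fit with one significance-based pruning pass
#'
#' Fits the joint Cox model on the screened candidates, drops covariates
#' with Wald p at or above `alpha` (default 0.05), and refits once on the
#' retained subset. The refitted hazard ratios are the ones used for point
#' assignment. When every screened covariate is already significant the
#' joint fit is returned as-is; when none is, an empty result is returned
#' with a warning.
#'
#' @param outcomes Outcome data frame.
#' @param covariates Data frame containing (at least) the screened columns.
#' @param screened Character vector of screened covariate names.
#' @param alpha Retention threshold in the joint model.
#' @return A `cox_fit` for the refitted model; the joint (pre-pruning) fit
#'   is attached as `attr(, "joint")`.
#' @export
multivariate_refit <- function(outcomes, covariates, screened, alpha = 0.05) {
  if (!length(screened)) stop("screened candidate set is empty")
  covariates <- as.data.frame(covariates)[, screened, drop = FALSE]
  joint <- fit_cox(outcomes, covariates)
  keep <- joint$term[joint$p < alpha]
  if (!length(keep)) {
    warning("no covariate significant in the joint model; empty score model")
    empty <- joint[0, , drop = FALSE]
    attr(empty, "joint") <- joint
    class(empty) <- class(joint)
    return(empty)
  }
  refit <- if (length(keep) == length(screened)) joint
           else fit_cox(outcomes, covariates[, keep, drop = FALSE])
  attr(refit, "joint") <- joint
  refit
}
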