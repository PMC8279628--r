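# Point-based score construction: the HR-band point rule, Youden cut-off
# derivation, assembly of score components from a refitted Cox model plus
# decile shape profiles, and per-patient score application.

#' Assign points to a predictor from its hazard ratio
#'
#' Predictors with hazard ratio inside the band 0.67--1.5 are worth
#' 1 point, predictors outside it 2 points. The band is closed at both
#' ends and implemented as `[1/1.5, 1.5]`, the log-symmetric reading of
#' its conventional printed form (0.67 is the rounded reciprocal of 1.5),
#' so a factor and its exact protective inverse always score alike.
#'
#' @param hr Positive hazard ratio(s).
#' @return Integer point value(s) in `{1, 2}`.
#' @export
assign_points <- function(hr) {
  if (any(!is.finite(hr) | hr <= 0)) stop("hazard ratio must be positive")
  ifelse(hr >= 1 / 1.5 & hr <= 1.5, 1L, 2L)
}

#' Youden-optimal dichotomization threshold
#'
#' Scans candidate thresholds — the midpoints between consecutive sorted
#' distinct values — and returns the one maximizing Youden's J
#' (sensitivity + specificity - 1) for the classifier "value above
#' threshold predicts the event". Ties in J are broken toward the lower
#' threshold.
#'
#' @param values Numeric, non-constant.
#' @param labels Binary event labels (0/1), both classes present.
#' @return The threshold; the maximal J is attached as `attr(, "youden_j")`.
#' @export
youden_cutoff <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  labels <- as.integer(labels[ok])
  if (length(unique(labels)) < 2) stop("both classes must be present")
  uv <- sort(unique(values))
  if (length(uv) < 2) stop("values are constant")
  cand <- (uv[-length(uv)] + uv[-1]) / 2
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  # cumulative counts of each class at or below each distinct value
  ord <- order(values)
  v_sorted <- values[ord]
  l_sorted <- labels[ord]
  cum1 <- cumsum(l_sorted == 1)
  cum0 <- cumsum(l_sorted == 0)
  pos <- cumsum(tabulate(match(v_sorted, uv), length(uv)))  # index of last row <= uv[i]
  at_or_below1 <- cum1[pos]
  at_or_below0 <- cum0[pos]
  # threshold cand[i] sits between uv[i] and uv[i+1]
  sens <- (n1 - at_or_below1[-length(uv)]) / n1   # P(value > t | event)
  spec <- at_or_below0[-length(uv)] / n0          # P(value <= t | no event)
  j <- sens + spec - 1
  best <- which.max(j)  # first (lowest-threshold) maximum
  structure(cand[best], youden_j = j[best])
}

#' Build a point-based score specification
#'
#' Turns the refitted multivariate Cox model plus the decile shape profiles
#' into an ordered list of score components:
#' \itemize{
#'   \item binary predictors score their points when present
#'     (`above_scores`);
#'   \item continuous predictors with a J/U-shaped profile become interval
#'     components: values outside the profile's zero-point band
#'     `[cutoff_low, cutoff_high]` score the points (`outside_scores`);
#'   \item other continuous predictors are dichotomized at the
#'     Youden-optimal threshold against the event label, scoring above the
#'     threshold when the refitted HR exceeds 1 and below it otherwise.
#' }
#' Per-unit hazard ratios of continuous predictors would make the point
#' band vacuous, so after cut-off derivation all components are coded as
#' indicators, the multivariate model is refitted once on the indicator
#' matrix, and those indicator HRs feed [assign_points()].
#'
#' @param refit A `cox_fit` from [multivariate_refit()].
#' @param profiles Named list of `decile_profile`s for the shape-profiled
#'   variables; every name must be a refitted predictor.
#' @param covariates Covariate data frame (cohort scale) containing the
#'   refitted predictors.
#' @param outcomes Outcome data frame aligned with `covariates`.
#' @param outcome_name Label stored in the spec.
#' @return Object of class `score_spec`: list with `outcome`, `components`
#'   (each: `variable`, `kind`, `direction`, `cutoff_low`/`cutoff_high` or
#'   `cutoff`, `points`, `hr`), `max_score`, and the indicator refit in
#'   `attr(, "indicator_fit")`.
#' @export
build_score_spec <- function(refit, profiles = list(), covariates, outcomes,
                             outcome_name = "event") {
  stopifnot(inherits(refit, "cox_fit"))
  vars <- refit$term
  bad <- setdiff(names(profiles), vars)
  if (length(bad))
    stop("profile supplied for variable(s) absent from the refitted model: ",
         paste(bad, collapse = ", "))
  if (!length(vars)) {
    spec <- structure(list(outcome = outcome_name, components = list(),
                           max_score = 0L), class = "score_spec")
    return(spec)
  }
  if (!is.null(outcomes$excluded)) {
    keep <- !outcomes$excluded
    outcomes <- outcomes[keep, , drop = FALSE]
    covariates <- covariates[keep, , drop = FALSE]
  }
  components <- list()
  indicators <- data.frame(row.names = seq_len(nrow(covariates)))
  for (nm in vars) {
    x <- covariates[[nm]]
    if (is.null(x)) stop("covariate '", nm, "' missing from the cohort table")
    hr_refit <- refit$hr[refit$term == nm]
    is_binary <- all(stats::na.omit(unique(x)) %in% c(0, 1))
    if (is_binary) {
      comp <- list(variable = nm, kind = "binary", direction = "above_scores")
      indicators[[nm]] <- as.numeric(x)
    } else if (nm %in% names(profiles) && profiles[[nm]]$shape == "J_or_U") {
      pr <- profiles[[nm]]
      comp <- list(variable = nm, kind = "continuous_interval",
                   direction = "outside_scores",
                   cutoff_low = pr$cutoff_low, cutoff_high = pr$cutoff_high)
      indicators[[nm]] <- as.numeric(x < pr$cutoff_low | x > pr$cutoff_high)
    } else {
      cc <- !is.na(x)
      if (hr_refit > 1) {
        thr <- youden_cutoff(x[cc], outcomes$event[cc])
        comp <- list(variable = nm, kind = "continuous_threshold",
                     direction = "above_scores", cutoff = as.numeric(thr))
        indicators[[nm]] <- as.numeric(x > thr)
      } else {
        thr <- -youden_cutoff(-x[cc], outcomes$event[cc])
        comp <- list(variable = nm, kind = "continuous_threshold",
                     direction = "below_scores", cutoff = as.numeric(thr))
        indicators[[nm]] <- as.numeric(x < thr)
      }
    }
    components[[nm]] <- comp
  }
  ind_fit <- fit_cox(outcomes, indicators)
  for (nm in vars) {
    hr <- ind_fit$hr[ind_fit$term == nm]
    components[[nm]]$hr <- hr
    pts <- assign_points(hr)
    # protective indicator (HR < 0.67): absence of the protective factor
    # carries the risk, so the trigger direction is flipped
    if (hr < 1 / 1.5) {
      components[[nm]]$direction <- switch(components[[nm]]$direction,
        above_scores = "below_scores", below_scores = "above_scores",
        outside_scores = "outside_scores")
      if (components[[nm]]$kind == "binary")
        components[[nm]]$kind <- "binary_absent"
    }
    components[[nm]]$points <- as.integer(pts)
  }
  components <- unname(components)
  spec <- structure(list(outcome = outcome_name, components = components,
                         max_score = sum(vapply(components, `[[`, integer(1), "points"))),
                    class = "score_spec")
  attr(spec, "indicator_fit") <- ind_fit
  spec
}

component_trigger <- function(comp, x) {
  switch(paste(comp$kind, comp$direction, sep = "."),
    binary.above_scores = x == 1,
    binary_absent.below_scores = x == 0,
    continuous_threshold.above_scores = x > comp$cutoff,
    continuous_threshold.below_scores = x < comp$cutoff,
    continuous_interval.outside_scores = x < comp$cutoff_low | x > comp$cutoff_high,
    stop("unknown component kind/direction: ", comp$kind, "/", comp$direction))
}

#' Apply a score specification to patients
#'
#' Sums the points of every triggered component. For an `outside_scores`
#' interval component a value inside the closed band contributes nothing.
#' Missing covariates follow `missing_policy`: `propagate_missing` (default)
#' yields `NA` for the patient's total, `score_as_zero` treats the component
#' as untriggered.
#'
#' @param spec A `score_spec`.
#' @param covariates Data frame with one row per patient.
#' @param missing_policy `"propagate_missing"` or `"score_as_zero"`.
#' @return Integer vector of scores in `[0, max_score]` (NA allowed under
#'   `propagate_missing`).
#' @export
apply_score <- function(spec, covariates,
                        missing_policy = c("propagate_missing", "score_as_zero")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(spec, "score_spec"))
  n <- nrow(covariates)
  total <- rep(0L, n)
  any_na <- rep(FALSE, n)
  for (comp in spec$components) {
    x <- covariates[[comp$variable]]
    if (is.null(x)) stop("covariate '", comp$variable, "' missing from input")
    trig <- component_trigger(comp, x)
    nas <- is.na(trig)
    any_na <- any_na | nas
    trig[nas] <- FALSE
    total <- total + comp$points * as.integer(trig)
  }
  if (missing_policy == "propagate_missing") total[any_na] <- NA_integer_
  total
}

#' @export
print.score_spec <- function(x, ...) {
  cat(sprintf("Point-based risk score for '%s' (max %d points)\n",
              x$outcome, x$max_score))
  if (!length(x$components)) {
    cat("  (empty score)\n")
    return(invisible(x))
  }
  for (comp in x$components) {
    rule <- switch(paste(comp$kind, comp$direction, sep = "."),
      binary.above_scores = "present",
      binary_absent.below_scores = "absent",
      continuous_threshold.above_scores = sprintf("> %.4g", comp$cutoff),
      continuous_threshold.below_scores = sprintf("< %.4g", comp$cutoff),
      continuous_interval.outside_scores =
        sprintf("outside [%.4g, %.4g]", comp$cutoff_low, comp$cutoff_high))
    cat(sprintf("  %-22s %-22s %d point%s  (HR %.3f)\n", comp$variable, rule,
                comp$points, if (comp$points > 1) "s" else " ", comp$hr))
  }
  invisible(x)
}

#' Serialize a score specification to JSON
#'
#' @param spec A `score_spec`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_score_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a score specification from JSON
#'
#' @param path File written by [write_score_spec()].
#' @return A `score_spec`.
#' @export
read_score_spec <- function(path) {
  raw <- jsonlite::read_json(path)
  raw$components <- lapply(raw$components, function(cmp) {
    cmp$points <- as.integer(cmp$points)
    cmp
  })
  raw$max_score <- as.integer(raw$max_score)
  structure(raw, class = "score_spec")
}
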