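# Decile hazard-ratio profiling: detect J/U-shaped exposure-outcome
# relationships and derive the cut-offs that define the zero-point band of
# a score component.

#' Decile hazard-ratio profile of a continuous exposure
#'
#' Patients are assigned to sample deciles of the exposure (right-closed
#' bins, so values tied with a boundary fall in the lower bin; bins can be
#' unequal under heavy ties). Two passes of univariate Cox regression
#' follow. First pass: each decile in turn is contrasted against the rest of
#' the cohort via a single indicator, and the interior decile (2-9) with the
#' minimal hazard ratio becomes the reference (ties go to the lowest index).
#' Second pass: one Cox model on the decile factor with the reference as
#' baseline gives each decile's HR, 95% CI and Wald p versus the reference.
#' A decile with zero events gets a missing HR with a warning.
#'
#' The returned profile carries a shape label from [classify_shape()] and,
#' for J/U-shaped profiles, the cut-offs from [derive_shape_cutoffs()].
#'
#' @param outcomes Outcome data frame (`time_days`, `event`; excluded rows
#'   dropped).
#' @param x Numeric exposure values aligned with `outcomes`.
#' @param variable Name of the exposure (for labelling).
#' @return Object of class `decile_profile`: list with `variable`, `breaks`
#'   (11 bin edges), `table` (per-decile n, events, first-pass HR, HR vs
#'   reference, CI, p), `reference_index`, `shape`, `cutoff_low`,
#'   `cutoff_high`.
#' @export
decile_hr_profile <- function(outcomes, x, variable = deparse(substitute(x))) {
  if (!is.null(outcomes$excluded)) {
    keep <- !outcomes$excluded
    outcomes <- outcomes[keep, , drop = FALSE]
    x <- x[keep]
  }
  ok <- !is.na(x)
  outcomes <- outcomes[ok, , drop = FALSE]
  x <- x[ok]
  if (length(unique(x)) < 10) stop("need at least 10 distinct exposure values")
  breaks <- unname(stats::quantile(x, probs = seq(0, 1, 0.1), type = 7))
  ub <- unique(breaks)
  if (length(ub) < 11)
    warning("heavy ties: fewer than 10 distinct decile boundaries; bins collapsed")
  dec <- .bincode(x, breaks = ub, right = TRUE, include.lowest = TRUE)
  k <- length(ub) - 1L
  nk <- tabulate(dec, k)
  evk <- vapply(seq_len(k), function(i) sum(outcomes$event[dec == i]), numeric(1))
  if (sum(evk > 0) < 2) stop("events present in fewer than 2 deciles")
  if (any(evk == 0))
    warning("decile(s) with zero events: ",
            paste(which(evk == 0), collapse = ", "), "; HR recorded as missing")

  # First pass: decile-vs-rest univariate HRs to locate the reference.
  first_hr <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    if (evk[i] == 0) next
    f <- fit_cox(outcomes, data.frame(ind = as.integer(dec == i)))
    first_hr[i] <- f$hr[1]
  }
  ref <- select_reference(first_hr)

  # Second pass: decile factor with the reference as baseline.
  fct <- stats::relevel(factor(dec, levels = seq_len(k)), ref = as.character(ref))
  dat <- data.frame(.time = outcomes$time_days, .event = outcomes$event, dec = fct)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ dec, data = dat,
                         ties = "breslow")
  s <- summary(fit)$coefficients
  hr <- rep(NA_real_, k); lo <- rep(NA_real_, k); hi <- rep(NA_real_, k)
  pv <- rep(NA_real_, k)
  hr[ref] <- 1
  for (i in setdiff(seq_len(k), ref)) {
    rn <- paste0("dec", i)
    if (!rn %in% rownames(s) || evk[i] == 0) next
    hr[i] <- exp(s[rn, "coef"])
    lo[i] <- exp(s[rn, "coef"] - 1.96 * s[rn, "se(coef)"])
    hi[i] <- exp(s[rn, "coef"] + 1.96 * s[rn, "se(coef)"])
    pv[i] <- s[rn, "Pr(>|z|)"]
  }
  prof <- structure(list(
    variable = variable,
    breaks = ub,
    table = data.frame(decile = seq_len(k), n = nk, events = evk,
                       first_pass_hr = first_hr, hr = hr, lower = lo,
                       upper = hi, p = pv),
    reference_index = ref
  ), class = "decile_profile")
  prof$shape <- classify_shape(prof)
  if (prof$shape == "J_or_U") {
    cuts <- derive_shape_cutoffs(prof)
    prof$cutoff_low <- cuts[[1]]
    prof$cutoff_high <- cuts[[2]]
  } else {
    prof$cutoff_low <- NA_real_
    prof$cutoff_high <- NA_real_
  }
  prof
}

# Reference selection rule: the interior decile (first and last excluded)
# with the minimal first-pass HR; ties and which.min both resolve to the
# lowest index. Missing HRs (zero-event deciles) are not eligible.
select_reference <- function(first_hr) {
  k <- length(first_hr)
  interior <- 2:(k - 1)
  cand <- interior[!is.na(first_hr[interior])]
  if (!length(cand)) stop("no interior decile with events to serve as reference")
  cand[which.min(first_hr[cand])]
}

#' Classify the shape of a decile hazard-ratio profile
#'
#' `J_or_U` when at least one decile below the reference and at least one
#' above it have HR significantly greater than 1 (Wald p < 0.05, HR > 1);
#' `linear` when only one side is significantly elevated; `flat` when
#' neither is. The reference decile itself is never tested.
#'
#' @param profile A `decile_profile`.
#' @return One of `"J_or_U"`, `"linear"`, `"flat"`.
#' @export
classify_shape <- function(profile) {
  tab <- profile$table
  ref <- profile$reference_index
  sig_elev <- !is.na(tab$p) & tab$p < 0.05 & tab$hr > 1
  below <- any(sig_elev[tab$decile < ref])
  above <- any(sig_elev[tab$decile > ref])
  if (below && above) "J_or_U" else if (below || above) "linear" else "flat"
}

#' Derive score cut-offs from a J/U-shaped profile
#'
#' Finds the maximal contiguous run of deciles containing the reference
#' whose HR does not differ significantly from the reference (Wald
#' p >= 0.05). The cut-offs are the outer boundary values of that run:
#' patients with exposure inside `[cutoff_low, cutoff_high]` score zero for
#' the component, patients outside score its points. A decile with a
#' missing HR (zero events) breaks the run: no claim of non-difference can
#' be made for it. If the run collapses to the reference decile alone its
#' own boundaries are returned, with a warning.
#'
#' @param profile A `decile_profile` with shape `J_or_U`.
#' @return Named numeric vector `c(cutoff_low, cutoff_high)` on the
#'   exposure scale.
#' @export
derive_shape_cutoffs <- function(profile) {
  tab <- profile$table
  ref <- profile$reference_index
  k <- nrow(tab)
  nonsig <- !is.na(tab$p) & tab$p >= 0.05
  nonsig[ref] <- TRUE
  lo <- ref
  while (lo > 1 && nonsig[lo - 1]) lo <- lo - 1
  hi <- ref
  while (hi < k && nonsig[hi + 1]) hi <- hi + 1
  if (lo == ref && hi == ref)
    warning("cut-off run collapsed to the reference decile alone")
  c(cutoff_low = profile$breaks[lo], cutoff_high = profile$breaks[hi + 1])
}

#' @export
print.decile_profile <- function(x, digits = 3, ...) {
  cat(sprintf("Decile hazard-ratio profile of '%s'\n", x$variable))
  cat(sprintf("  reference decile: %d   shape: %s\n", x$reference_index, x$shape))
  if (!is.na(x$cutoff_low))
    cat(sprintf("  zero-point band: [%.4g, %.4g]\n", x$cutoff_low, x$cutoff_high))
  tab <- x$table
  for (nm in c("first_pass_hr", "hr", "lower", "upper")) tab[[nm]] <- round(tab[[nm]], digits)
  tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot a decile hazard-ratio profile
#'
#' Per-decile hazard ratios versus the reference with 95% confidence
#' intervals on a log scale, against the decile midpoints of the exposure.
#'
#' @param x A `decile_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.decile_profile <- function(x, ...) {
  tab <- x$table
  mids <- (x$breaks[-length(x$breaks)] + x$breaks[-1]) / 2
  ok <- !is.na(tab$hr)
  ylim <- range(c(tab$lower[!is.na(tab$lower)], tab$upper[!is.na(tab$upper)], 1))
  graphics::plot(mids[ok], tab$hr[ok], log = "y", pch = 19,
                 xlab = x$variable, ylab = "hazard ratio vs reference decile",
                 ylim = ylim, ...)
  graphics::segments(mids[ok], pmax(tab$lower[ok], 1e-8), mids[ok], tab$upper[ok])
  graphics::abline(h = 1, lty = 2)
  graphics::points(mids[x$reference_index], 1, pch = 1, cex = 2)
  if (!is.na(x$cutoff_low))
    graphics::abline(v = c(x$cutoff_low, x$cutoff_high), lty = 3)
  invisible(x)
}
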