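# Synthetic diabetes-cohort generator with known ground truth.
#
# Covariates are drawn from a Gaussian copula: correlated latent standard
# normals are transformed to the target marginals (normal, lognormal, or
# binary by thresholding at the prevalence quantile). Event times follow a
# proportional-hazards model with Weibull baseline
#   h(t|x) = (k/lambda) * (t/lambda)^(k-1) * exp(lp(x)),
#   lp(x)  = sum_j beta_j * (x_j - c_j) + gamma * (x_u - nadir)^2,
# where c_j is the configured mean for continuous covariates and 0 for
# binaries, so the baseline refers to a comorbidity-free patient at average
# lab values. gamma > 0 produces a J/U-shaped log-hazard in x_u with its
# nadir at `nadir`. Death is an independent exponential censoring process;
# follow-up ends at the administrative horizon.

#' Default covariate specifications
#'
#' Eleven mixed-type covariates emulating a middle-aged type 2 diabetes
#' cohort: age (years), male sex, five binary comorbidity/flag variables
#' (hypertension, ischaemic heart disease, heart failure, atrial
#' fibrillation, baseline anaemia), and four continuous labs (window-mean
#' HbA1c %, HDL-C mmol/L, total cholesterol mmol/L, creatinine umol/L,
#' the last lognormal).
#'
#' @return List of per-covariate specs (`name`, `type`, parameters).
#' @export
default_covariates <- function() {
  list(
    list(name = "age", type = "normal", mean = 66, sd = 11.8),
    list(name = "sex_male", type = "binary", prevalence = 0.476),
    list(name = "hypertension", type = "binary", prevalence = 0.231),
    list(name = "ihd", type = "binary", prevalence = 0.077),
    list(name = "heart_failure", type = "binary", prevalence = 0.035),
    list(name = "atrial_fibrillation", type = "binary", prevalence = 0.028),
    list(name = "anaemia", type = "binary", prevalence = 0.143),
    list(name = "hba1c_mean", type = "normal", mean = 7.67, sd = 1.17),
    list(name = "hdl_c", type = "normal", mean = 1.20, sd = 0.34),
    list(name = "chol_total", type = "normal", mean = 4.84, sd = 1.03),
    list(name = "creatinine", type = "lognormal", meanlog = log(95), sdlog = 0.45)
  )
}

default_correlation <- function(names) {
  r <- diag(length(names))
  dimnames(r) <- list(names, names)
  set_r <- function(a, b, v) {
    if (a %in% names && b %in% names) {
      r[a, b] <<- v
      r[b, a] <<- v
    }
  }
  set_r("hba1c_mean", "chol_total", 0.20)
  set_r("hdl_c", "chol_total", 0.25)
  set_r("age", "ihd", 0.15)
  set_r("age", "atrial_fibrillation", 0.15)
  set_r("age", "anaemia", 0.10)
  set_r("heart_failure", "ihd", 0.20)
  r
}

#' Simulation configuration
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; all draws come from one stream seeded here
#'   (order: latent covariate normals, event uniforms, death times, extra
#'   episode counts).
#' @param covariates Covariate specs as in [default_covariates()].
#' @param correlation Latent-normal correlation matrix (named, positive
#'   semi-definite). Defaults to a sparse clinically plausible pattern.
#' @param effects Named numeric vector of per-unit log hazard ratios.
#' @param ushape Optional list `(variable, nadir, gamma)` adding a quadratic
#'   log-hazard term `gamma * (x - nadir)^2` (gamma per unit squared).
#' @param baseline List `(shape, scale)` of the Weibull baseline, scale in
#'   years.
#' @param horizon_years Administrative censoring horizon.
#' @param death_rate Rate (per year) of the independent exponential death
#'   process that censors follow-up.
#' @param extra_episode_rate Poisson rate (per remaining follow-up year) of
#'   additional episodes attached to patients who experience the event.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 20000,
                       seed = 1L,
                       covariates = default_covariates(),
                       correlation = NULL,
                       effects = c(age = log(1.02), sex_male = log(1.07),
                                   anaemia = log(1.18), hdl_c = log(0.802),
                                   ihd = log(1.59), hypertension = log(1.16),
                                   hba1c_mean = log(1.16)),
                       ushape = NULL,
                       baseline = list(shape = 1.2, scale = 87),
                       horizon_years = 11,
                       death_rate = 0.037,
                       extra_episode_rate = 0) {
  names_cov <- vapply(covariates, `[[`, character(1), "name")
  if (is.null(correlation)) correlation <- default_correlation(names_cov)
  stopifnot(n_patients >= 1, horizon_years > 0,
            identical(dim(correlation), c(length(names_cov), length(names_cov))))
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  unknown <- setdiff(names(effects), names_cov)
  if (length(unknown)) stop("effects name unknown covariate(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(ushape)) {
    stopifnot(is.list(ushape), all(c("variable", "nadir", "gamma") %in% names(ushape)))
    if (!ushape$variable %in% names_cov) stop("ushape variable not a covariate")
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 covariates = covariates, correlation = correlation,
                 effects = effects, ushape = ushape, baseline = baseline,
                 horizon_years = horizon_years, death_rate = death_rate,
                 extra_episode_rate = extra_episode_rate,
                 covariate_names = names_cov),
            class = "sim_config")
}

#' Generate the covariate table
#'
#' Correlated latent standard normals (Gaussian copula) are transformed to
#' each covariate's marginal: normal and lognormal by location/scale,
#' binary by thresholding the latent normal at the upper `prevalence`
#' quantile. Reproducible given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Data frame with `patient_id` and one column per covariate.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  p <- length(config$covariates)
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol(config$correlation)
  out <- data.frame(patient_id = sprintf("P%07d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    sp <- config$covariates[[j]]
    out[[sp$name]] <- switch(sp$type,
      normal = sp$mean + sp$sd * z[, j],
      lognormal = exp(sp$meanlog + sp$sdlog * z[, j]),
      binary = as.integer(z[, j] > stats::qnorm(1 - sp$prevalence)),
      stop("unknown covariate type: ", sp$type))
  }
  out
}

# Centered linear predictor including the optional quadratic shape term.
sim_linear_predictor <- function(cohort, config) {
  lp <- rep(0, nrow(cohort))
  centers <- sim_centers(config)
  for (nm in names(config$effects))
    lp <- lp + config$effects[[nm]] * (cohort[[nm]] - centers[[nm]])
  if (!is.null(config$ushape))
    lp <- lp + config$ushape$gamma * (cohort[[config$ushape$variable]] - config$ushape$nadir)^2
  if (any(!is.finite(lp))) stop("non-finite linear predictor")
  lp
}

sim_centers <- function(config) {
  cs <- lapply(config$covariates, function(sp) switch(sp$type,
    normal = sp$mean, lognormal = exp(sp$meanlog + sp$sdlog^2 / 2), binary = 0))
  names(cs) <- config$covariate_names
  cs
}

#' Simulate right-censored event times for a generated cohort
#'
#' Inverse-transform sampling from the Weibull-baseline proportional-hazards
#' model: with `U ~ Unif(0,1)`,
#' `T = scale * (-log(U) / exp(lp))^(1/shape)` years. Follow-up is censored
#' at the earlier of an independent exponential death time and the
#' administrative horizon. Times are reported in whole days (ceiling).
#'
#' Call after [generate_covariates()] under the same config: draws continue
#' the seeded stream, so `generate_covariates` + `simulate_event_times` is
#' reproducible end to end.
#'
#' @param cohort Data frame from [generate_covariates()].
#' @param config A [sim_config()].
#' @return Data frame with `patient_id`, `time_days`, `event`,
#'   `episode_count`, `excluded`, `exclusion_reason`, and the latent
#'   `death_days` (NA when the patient outlives the horizon) used when
#'   exporting raw tables.
#' @export
simulate_event_times <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(cohort)
  lp <- sim_linear_predictor(cohort, config)
  u <- stats::runif(n)
  t_event <- config$baseline$scale * (-log(u) / exp(lp))^(1 / config$baseline$shape)
  t_death <- stats::rexp(n, rate = config$death_rate)
  t_cens <- pmin(t_death, config$horizon_years)
  event <- as.integer(t_event <= t_cens)
  t_obs <- pmin(t_event, t_cens)
  time_days <- pmax(1L, as.integer(ceiling(t_obs * 365.25)))
  count <- event
  if (config$extra_episode_rate > 0) {
    extra <- stats::rpois(n, config$extra_episode_rate * pmax(config$horizon_years - t_obs, 0))
    count <- count + ifelse(event == 1L, extra, 0L)
  }
  data.frame(patient_id = cohort$patient_id, time_days = time_days,
             event = event, episode_count = count,
             excluded = FALSE, exclusion_reason = NA_character_,
             death_days = ifelse(t_death < config$horizon_years,
                                 as.integer(ceiling(t_death * 365.25)), NA_integer_),
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort (covariates plus outcomes)
#'
#' @param config A [sim_config()].
#' @return List with `covariates`, `outcomes`, `truth` (true effects, shape
#'   spec and baseline) and the `config`.
#' @export
simulate_cohort <- function(config) {
  cov <- generate_covariates(config)
  out <- simulate_event_times(cov, config)
  list(covariates = cov, outcomes = out,
       truth = list(effects = as.list(config$effects), ushape = config$ushape,
                    baseline = config$baseline, death_rate = config$death_rate,
                    horizon_years = config$horizon_years),
       config = config)
}

#' Export a simulated cohort in the raw three-table format
#'
#' Writes `patients.csv`, `episodes.csv`, `labs.csv` (the format
#' [read_cohort_tables()] consumes) plus `truth.json` with the generative
#' ground truth. The mapping: every patient gets a diabetes diagnosis code
#' inside the recruitment window; binary comorbidities become pre-index
#' diagnosis codes; anaemia and the continuous labs become baseline-window
#' measurements (haemoglobin set consistently with the anaemia flag);
#' window-mean HbA1c becomes a single measurement in the mean-lab window;
#' the simulated event becomes an `AMI` or `SCD` episode at
#' index + `time_days`; death during follow-up becomes `death_date`.
#'
#' With `outcome = "SCD"`, `ami_contamination` gives the fraction of
#' event patients that additionally receive an AMI episode (half linked
#' within the 7-day window, half well before the SCD), so that
#' [derive_outcome()]'s exclusion paths are exercised.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param outcome `"AMI"` or `"SCD"` episode kind for the simulated event.
#' @param config A [study_config()] giving the calendar frame.
#' @param ami_contamination Fraction of SCD-event patients given an AMI
#'   episode (ignored for `outcome = "AMI"`).
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(sim, dir, outcome = c("AMI", "SCD"),
                                config = study_config(),
                                ami_contamination = 0) {
  outcome <- match.arg(outcome)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cov <- sim$covariates
  out <- sim$outcomes
  idx <- config$index_date
  n <- nrow(cov)

  birth <- idx - round(cov$age * 365.25)
  death <- as.Date(rep(NA, n))
  died <- out$event == 0L & !is.na(out$death_days) & out$death_days <= out$time_days
  death[died] <- idx + out$time_days[died]
  patients <- data.frame(patient_id = cov$patient_id,
                         sex = ifelse(cov$sex_male == 1, "male", "female"),
                         birth_date = birth, death_date = death,
                         stringsAsFactors = FALSE)

  ep <- list(data.frame(patient_id = cov$patient_id,
                        episode_date = idx + 150, kind = "diagnosis_code",
                        code = "250.00", stringsAsFactors = FALSE))
  comorb_codes <- c(hypertension = "401.9", ihd = "414.0",
                    heart_failure = "428.0", atrial_fibrillation = "427.31")
  for (nm in names(comorb_codes)) {
    has <- cov[[nm]] == 1
    if (any(has))
      ep[[length(ep) + 1L]] <- data.frame(patient_id = cov$patient_id[has],
                                          episode_date = idx - 200,
                                          kind = "diagnosis_code",
                                          code = comorb_codes[[nm]],
                                          stringsAsFactors = FALSE)
  }
  has_ev <- out$event == 1L
  if (any(has_ev))
    ep[[length(ep) + 1L]] <- data.frame(patient_id = cov$patient_id[has_ev],
                                        episode_date = idx + out$time_days[has_ev],
                                        kind = outcome, code = outcome,
                                        stringsAsFactors = FALSE)
  if (outcome == "SCD" && ami_contamination > 0 && any(has_ev)) {
    ids <- which(has_ev)
    n_cont <- floor(length(ids) * ami_contamination)
    if (n_cont >= 1) {
      pick <- ids[seq_len(n_cont)]  # deterministic given the sim
      half <- ceiling(n_cont / 2)
      linked <- pick[seq_len(half)]
      prior <- setdiff(pick, linked)
      ep[[length(ep) + 1L]] <- data.frame(patient_id = cov$patient_id[linked],
                                          episode_date = idx + out$time_days[linked] - 3,
                                          kind = "AMI", code = "AMI",
                                          stringsAsFactors = FALSE)
      if (length(prior)) {
        d <- pmax(out$time_days[prior] - 100, 1)
        ep[[length(ep) + 1L]] <- data.frame(patient_id = cov$patient_id[prior],
                                            episode_date = idx + d,
                                            kind = "AMI", code = "AMI",
                                            stringsAsFactors = FALSE)
      }
    }
  }
  episodes <- do.call(rbind, ep)

  base_date <- config$baseline_lab_window[1] + 165
  mean_date <- config$mean_lab_window[1] + 500
  hb <- ifelse(cov$anaemia == 1, ifelse(cov$sex_male == 1, 12.2, 11.2),
               ifelse(cov$sex_male == 1, 14.5, 13.5))
  labs <- rbind(
    data.frame(patient_id = cov$patient_id, lab_name = "haemoglobin",
               value = hb, measured_date = base_date, stringsAsFactors = FALSE),
    data.frame(patient_id = cov$patient_id, lab_name = "hdl_c",
               value = cov$hdl_c, measured_date = base_date, stringsAsFactors = FALSE),
    data.frame(patient_id = cov$patient_id, lab_name = "chol_total",
               value = cov$chol_total, measured_date = base_date, stringsAsFactors = FALSE),
    data.frame(patient_id = cov$patient_id, lab_name = "creatinine",
               value = cov$creatinine, measured_date = base_date, stringsAsFactors = FALSE),
    data.frame(patient_id = cov$patient_id, lab_name = "hba1c",
               value = cov$hba1c_mean, measured_date = mean_date, stringsAsFactors = FALSE)
  )

  utils::write.csv(patients, file.path(dir, "patients.csv"), row.names = FALSE, na = "")
  utils::write.csv(episodes, file.path(dir, "episodes.csv"), row.names = FALSE, na = "")
  utils::write.csv(labs, file.path(dir, "labs.csv"), row.names = FALSE, na = "")
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
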