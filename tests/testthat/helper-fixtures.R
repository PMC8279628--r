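# Small in-code fixtures for the cohort engine tests.

fixture_config <- function(...) study_config(...)

# A patients table whose rows exercise each inclusion rule.
fixture_patients <- function() {
  idx <- as.Date("2009-01-01")
  data.frame(
    patient_id = c("A", "B", "C", "D"),
    sex = c("male", "female", "male", "female"),
    # A is exactly 40 at index; the others are comfortably older
    birth_date = c(idx - round(40 * 365.25), as.Date("1950-06-15"),
                   as.Date("1945-03-02"), as.Date("1955-11-30")),
    death_date = as.Date(c(NA, NA, NA, NA)),
    stringsAsFactors = FALSE
  )
}

fixture_episodes <- function() {
  data.frame(
    patient_id = c("A", "B", "C", "B"),
    episode_date = as.Date(c("2009-03-01", "2009-02-01", "2009-05-01", "2007-06-01")),
    kind = c("diagnosis_code", "diagnosis_code", "prescription", "AMI"),
    code = c("250.01", "250.40", "ADRX1", "410.1"),
    stringsAsFactors = FALSE
  )
}

fixture_labs <- function() {
  data.frame(
    patient_id = c("A", "B", "C", "D"),
    lab_name = "haemoglobin",
    value = c(14, 11.5, 13.5, 12.5),
    measured_date = as.Date("2008-06-01"),
    stringsAsFactors = FALSE
  )
}

# Cached U-shape simulation replicates shared by the shape-recovery and
# cut-off-recovery acceptance checks (computed once per test run).
.ushape_cache <- new.env(parent = emptyenv())

ushape_replicates <- function(n_rep = 50, n = 20000, gamma = 0.6) {
  key <- sprintf("g%s", gamma)
  if (!is.null(.ushape_cache[[key]])) return(.ushape_cache[[key]])
  nadir <- 7.67 + qnorm(0.4) * 1.17  # 40th percentile of the exposure
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(
      n_patients = n, seed = 52200 + r,
      covariates = list(list(name = "hba1c_mean", type = "normal",
                             mean = 7.67, sd = 1.17)),
      effects = c(),
      ushape = if (gamma > 0) list(variable = "hba1c_mean", nadir = nadir,
                                   gamma = gamma) else NULL
    )
    sim <- simulate_cohort(cfg)
    # null replicates legitimately warn (collapsed cut-off runs etc.)
    prof <- suppressWarnings(
      decile_hr_profile(sim$outcomes, sim$covariates$hba1c_mean,
                        variable = "hba1c_mean"))
    out[[r]] <- list(reference = prof$reference_index, shape = prof$shape,
                     cutoff_low = prof$cutoff_low, cutoff_high = prof$cutoff_high,
                     nadir = nadir)
  }
  .ushape_cache[[key]] <- out
  out
}
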