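test_that("diabetes onset is the earliest qualifying record, with strict lab thresholds", {
  cfg <- fixture_config()
  rec <- data.frame(patient_id = "X", birth_date = as.Date("1950-01-01"))
  eps <- data.frame(patient_id = "X", episode_date = as.Date("2005-03-01"),
                    kind = "diagnosis_code", code = "250.00",
                    stringsAsFactors = FALSE)
  labs <- data.frame(
    patient_id = "X",
    lab_name = c("hba1c", "fbg"),
    value = c(6.8, 7.4),
    measured_date = as.Date(c("2004-06-01", "2006-01-01")),
    stringsAsFactors = FALSE)
  expect_equal(derive_diabetes_onset(rec, eps, labs, cfg), as.Date("2004-06-01"))

  # permutation invariance of record order
  expect_equal(derive_diabetes_onset(rec, eps, labs[2:1, ], cfg),
               as.Date("2004-06-01"))

  # HbA1c exactly at the threshold does not qualify (strict >)
  border <- data.frame(patient_id = "X", lab_name = "hba1c", value = 6.5,
                       measured_date = as.Date("2004-06-01"),
                       stringsAsFactors = FALSE)
  expect_true(is.na(derive_diabetes_onset(rec, eps[0, ], border, cfg)))

  # no qualifying evidence at all
  expect_true(is.na(derive_diabetes_onset(rec, eps[0, ], labs[0, ], cfg)))

  # lab predating birth is a validation error
  bad <- data.frame(patient_id = "X", lab_name = "hba1c", value = 8,
                    measured_date = as.Date("1940-01-01"), stringsAsFactors = FALSE)
  expect_error(derive_diabetes_onset(rec, eps, bad, cfg), "before birth")
})

test_that("inclusion partitions the input with per-rule exclusion counts", {
  cfg <- fixture_config()
  cohort <- apply_inclusion(fixture_patients(), fixture_episodes(), fixture_labs(), cfg)
  audit <- attr(cohort, "audit")

  # A: exactly 40 at index -> excluded under the strict 'above 40' rule
  # B: prior AMI in 2007 -> excluded
  # C: all three criteria met -> retained
  # D: no diabetes evidence -> excluded
  expect_equal(cohort$patient_id, "C")
  expect_equal(audit$exclusions$age_at_index, 1)
  expect_equal(audit$exclusions$prior_ami_scd, 1)
  expect_equal(audit$exclusions$no_diabetes_evidence, 1)
  expect_equal(audit$n_retained + sum(unlist(audit$exclusions)), audit$n_input)
})

test_that("anaemia flags follow the sex-specific strict thresholds", {
  expect_true(flag_anaemia("male", 12.9))
  expect_false(flag_anaemia("female", 12.0))
  expect_false(flag_anaemia("male", 13.0))
  expect_true(flag_anaemia("female", 11.9))
  expect_true(is.na(flag_anaemia("male", NA)))
  expect_error(flag_anaemia("male", -1), "positive")
})

test_that("window mean includes only values dated inside the closed window", {
  labs <- data.frame(
    patient_id = "X", lab_name = "hba1c",
    value = c(7, 8, 9, 99),
    measured_date = as.Date(c("2004-06-01", "2006-01-01", "2008-12-31", "2009-01-01")),
    stringsAsFactors = FALSE)
  w <- c("2004-01-01", "2008-12-31")
  expect_equal(window_mean_lab(labs, "hba1c", w), 8)
  expect_true(is.na(window_mean_lab(labs, "fbg", w)))
  expect_true(is.na(window_mean_lab(labs[0, ], "hba1c", w)))
})

test_that("SCD outcome applies the AMI-linkage and prior-AMI exclusions", {
  cfg <- fixture_config()
  idx <- cfg$index_date
  span <- as.integer(cfg$follow_up_end - idx)
  cohort <- data.frame(
    patient_id = c("S1", "S2", "S3", "S4", "S5", "S6"),
    sex = "male",
    birth_date = as.Date("1950-01-01"),
    death_date = as.Date(c(NA, NA, NA, NA, NA, NA)),
    age_at_index = 59, stringsAsFactors = FALSE)
  cohort$death_date[5] <- idx + 1000
  eps <- data.frame(
    patient_id = c("S1", "S1", "S2", "S2", "S4", "S6", "S6"),
    episode_date = idx + c(500, 495, 500, 100, 300, 400, 408),
    kind = c("SCD", "AMI", "SCD", "AMI", "SCD", "SCD", "AMI"),
    code = "x", stringsAsFactors = FALSE)

  out <- derive_outcome(cohort, eps, outcome = "non_AMI_SCD", config = cfg)
  audit <- attr(out, "audit")

  # S1: AMI 5 days before the SCD -> AMI-related, excluded
  expect_true(out$excluded[1])
  expect_equal(out$exclusion_reason[1], "ami_linked_scd")
  # S2: AMI 400 days before the SCD -> prior-AMI exclusion
  expect_true(out$excluded[2])
  expect_equal(out$exclusion_reason[2], "ami_prior_to_scd")
  # S3: no episode, alive -> censored at the end of follow-up
  expect_equal(out$event[3], 0L)
  expect_equal(out$time_days[3], span)
  # S4: clean SCD -> event at day 300
  expect_equal(out$event[4], 1L)
  expect_equal(out$time_days[4], 300L)
  expect_equal(out$episode_count[4], 1L)
  # S5: death without event -> censored at death
  expect_equal(out$event[5], 0L)
  expect_equal(out$time_days[5], 1000L)
  # S6: AMI 8 days after the SCD -> outside the 7-day linkage window, and
  # not prior to it -> a genuine non-AMI SCD event
  expect_false(out$excluded[6])
  expect_equal(out$event[6], 1L)
  expect_equal(out$time_days[6], 400L)

  expect_equal(audit$exclusions$ami_linked_scd, 1)
  expect_equal(audit$exclusions$ami_prior_to_scd, 1)

  # invariants: time within the follow-up span; event iff qualifying episode
  expect_true(all(out$time_days[!out$excluded] <= span))
  expect_true(all(out$time_days >= 0))

  # a target episode on/before index means inclusion failed upstream
  bad <- eps
  bad$episode_date[3] <- idx - 10
  expect_error(derive_outcome(cohort, bad, outcome = "non_AMI_SCD", config = cfg),
               "before index")
})

test_that("AMI-linkage boundary is 7 days inclusive", {
  cfg <- fixture_config()
  idx <- cfg$index_date
  cohort <- data.frame(patient_id = "P", sex = "male",
                       birth_date = as.Date("1950-01-01"),
                       death_date = as.Date(NA), age_at_index = 59,
                       stringsAsFactors = FALSE)
  eps7 <- data.frame(patient_id = "P", episode_date = idx + c(500, 507),
                     kind = c("SCD", "AMI"), code = "x", stringsAsFactors = FALSE)
  out7 <- derive_outcome(cohort, eps7, outcome = "non_AMI_SCD", config = cfg)
  expect_true(out7$excluded[1])  # exactly 7 days after -> linked
})

test_that("event rate summary matches hand arithmetic and scales linearly", {
  out <- toy_outcomes(time_days = c(5, 5) * 365.25, event = c(1, 1),
                      episode_count = c(2, 1))
  s <- event_rate_summary(out)
  expect_equal(s$annualized_rate_pct_per_year, 30)  # 3 episodes / 10 patient-years
  expect_equal(s$mean_annual_frequency, mean(c(2 / 5, 1 / 5)))

  # zero episodes: rate 0, mean frequency undefined
  none <- toy_outcomes(time_days = c(365.25, 730.5), event = c(0, 0),
                       episode_count = c(0, 0))
  s0 <- event_rate_summary(none)
  expect_equal(s0$annualized_rate_pct_per_year, 0)
  expect_true(is.na(s0$mean_annual_frequency))

  # doubling every episode count doubles the rate
  out2 <- out
  out2$episode_count <- out2$episode_count * 2
  expect_equal(event_rate_summary(out2)$annualized_rate_pct_per_year,
               2 * s$annualized_rate_pct_per_year)

  expect_error(event_rate_summary(toy_outcomes(numeric(0), integer(0))),
               "no patients")
  zero <- toy_outcomes(time_days = c(0, 0), event = c(0, 0))
  expect_error(event_rate_summary(zero), "patient-years")
})

test_that("annualized rate recovers the truth of a simulated episode process", {
  set.seed(61)
  n <- 10000
  years <- 10
  rate <- 0.05
  counts <- rpois(n, rate * years)
  out <- toy_outcomes(time_days = rep(years * 365.25, n),
                      event = as.integer(counts >= 1), episode_count = counts)
  est <- event_rate_summary(out)$annualized_rate_pct_per_year
  mc_se <- 100 * sd(counts) / (years * sqrt(n))
  expect_lt(abs(est - 100 * rate), 3 * mc_se)
})
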