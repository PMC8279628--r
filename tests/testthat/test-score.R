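test_that("the hazard-ratio band rule assigns points as printed", {
  expect_equal(assign_points(1.59), 2L)   # e.g. ischaemic heart disease
  expect_equal(assign_points(1.00), 1L)
  expect_equal(assign_points(0.50), 2L)
  expect_equal(assign_points(0.802), 1L)  # e.g. protective HDL-C
  # inclusive boundaries, symmetric on the log scale
  expect_equal(assign_points(1.5), 1L)
  expect_equal(assign_points(0.67), 1L)
  for (h in c(1.5, 1 / 1.5)) expect_equal(assign_points(h), assign_points(1 / h))
  expect_equal(assign_points(c(1.59, 1.0, 0.5)), c(2L, 1L, 2L))
  expect_error(assign_points(0), "positive")
  expect_error(assign_points(-2), "positive")
})

test_that("the Youden threshold equals the exhaustive scan", {
  set.seed(91)
  for (rep in 1:10) {
    n <- 200
    x <- round(rnorm(n), 2)
    y <- rbinom(n, 1, plogis(1.5 * x))
    if (length(unique(y)) < 2) next
    got <- youden_cutoff(x, y)
    want <- youden_brute(x, y)
    expect_equal(as.numeric(got), as.numeric(want))
    expect_equal(attr(got, "youden_j"), attr(want, "youden_j"))
  }
})

test_that("Youden threshold behaviour at separation and under the null", {
  # perfect separation: the midpoint of the gap between the classes
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  t <- youden_cutoff(x, y)
  expect_equal(as.numeric(t), 6.5)
  expect_equal(attr(t, "youden_j"), 1)

  # permuted labels: J at the chosen threshold is small
  set.seed(92)
  x2 <- rnorm(200)
  y2 <- sample(rep(0:1, 100))
  expect_lt(attr(youden_cutoff(x2, y2), "youden_j"), 0.3)

  expect_error(youden_cutoff(rep(1, 10), rep(0:1, 5)), "constant")
  expect_error(youden_cutoff(rnorm(10), rep(1, 10)), "both classes")
})

# A fixed two-component spec used for the application-semantics tests.
toy_spec <- function() {
  structure(list(
    outcome = "toy",
    components = list(
      list(variable = "bin", kind = "binary", direction = "above_scores",
           points = 2L, hr = 1.8),
      list(variable = "lab", kind = "continuous_interval",
           direction = "outside_scores", cutoff_low = 5, cutoff_high = 8,
           points = 1L, hr = 1.3),
      list(variable = "thr", kind = "continuous_threshold",
           direction = "above_scores", cutoff = 50, points = 1L, hr = 1.2)
    ),
    max_score = 4L), class = "score_spec")
}

test_that("score application honours interval and threshold semantics", {
  spec <- toy_spec()
  pts <- data.frame(bin = c(0, 1, 0, 0, 1, 0),
                    lab = c(6, 6, 4.9, 8.1, 9, 5),    # inside band scores 0
                    thr = c(40, 60, 40, 40, 60, NA))
  got <- apply_score(spec, pts)
  expect_equal(got[1:5], c(0L, 3L, 1L, 1L, 4L))
  expect_true(is.na(got[6]))                       # propagate_missing default
  expect_equal(apply_score(spec, pts, missing_policy = "score_as_zero")[6], 0L)

  # boundary values of the closed zero-point band score nothing
  edge <- data.frame(bin = 0, lab = c(5, 8), thr = 40)
  expect_equal(apply_score(spec, edge), c(0L, 0L))

  expect_error(apply_score(spec, data.frame(bin = 1)), "missing from input")
})

test_that("worsening one component never decreases the total score", {
  spec <- toy_spec()
  set.seed(93)
  pts <- data.frame(bin = rbinom(50, 1, 0.5), lab = runif(50, 3, 10),
                    thr = runif(50, 0, 100))
  base <- apply_score(spec, pts)
  worse <- pts
  worse$thr <- pts$thr + 60  # push everyone across the threshold
  expect_true(all(apply_score(spec, worse) >= base))
  worse2 <- pts
  worse2$bin <- 1
  expect_true(all(apply_score(spec, worse2) >= base))
})

test_that("score construction maps model structure onto component types", {
  # binary risk factor, a protective continuous lab, a U-shaped exposure
  set.seed(94)
  n <- 20000
  nadir <- 7.67 + qnorm(0.4) * 1.17
  cfg <- sim_config(
    n_patients = n, seed = 94,
    covariates = list(
      list(name = "ihd", type = "binary", prevalence = 0.1),
      list(name = "hdl_c", type = "normal", mean = 1.2, sd = 0.34),
      list(name = "hba1c_mean", type = "normal", mean = 7.67, sd = 1.17)),
    effects = c(ihd = log(1.8), hdl_c = log(0.45)),
    ushape = list(variable = "hba1c_mean", nadir = nadir, gamma = 0.3))
  sim <- simulate_cohort(cfg)
  dat <- cbind(sim$outcomes, sim$covariates)
  fit <- risk_score(survival::Surv(time_days, event) ~ ihd + hdl_c + hba1c_mean,
                    dat, profile_vars = "hba1c_mean", outcome_name = "toy")
  comp <- setNames(fit$spec$components,
                   vapply(fit$spec$components, `[[`, character(1), "variable"))
  expect_setequal(names(comp), c("ihd", "hdl_c", "hba1c_mean"))
  expect_equal(comp$ihd$kind, "binary")
  expect_equal(comp$ihd$direction, "above_scores")
  expect_equal(comp$hdl_c$kind, "continuous_threshold")
  expect_equal(comp$hdl_c$direction, "below_scores")  # protective lab
  expect_equal(comp$hba1c_mean$kind, "continuous_interval")
  expect_equal(comp$hba1c_mean$direction, "outside_scores")
  expect_true(all(vapply(comp, `[[`, integer(1), "points") %in% 1:2))
  expect_equal(fit$spec$max_score,
               sum(vapply(comp, `[[`, integer(1), "points")))

  # deterministic: rebuilding from the same fits gives the same spec
  spec2 <- build_score_spec(fit$refit, fit$profiles,
                            sim$covariates, sim$outcomes, outcome_name = "toy")
  expect_equal(spec2$components, fit$spec$components)
  expect_equal(spec2$max_score, fit$spec$max_score)

  # a profile for a variable outside the refitted model is an error
  rogue <- fit$profiles
  names(rogue) <- "nonexistent"
  expect_error(build_score_spec(fit$refit, rogue, sim$covariates, sim$outcomes),
               "absent from the refitted model")

  # scoring the cohort stays within [0, max_score]
  sc <- predict(fit)
  expect_true(all(sc >= 0 & sc <= fit$spec$max_score, na.rm = TRUE))
})

test_that("an empty refitted model yields an empty zero-point spec", {
  set.seed(95)
  n <- 2000
  out <- toy_outcomes(sample(1:4000, n, TRUE), rbinom(n, 1, 0.1))
  X <- data.frame(noise = rnorm(n))
  expect_warning(refit <- multivariate_refit(out, X, "noise", alpha = 1e-9),
                 "empty score model")
  spec <- build_score_spec(refit, list(), X, out)
  expect_equal(length(spec$components), 0L)
  expect_equal(spec$max_score, 0L)
  expect_equal(apply_score(spec, X), rep(0L, n))
})

test_that("score specifications survive a JSON round trip", {
  spec <- toy_spec()
  path <- withr::local_tempfile(fileext = ".json")
  write_score_spec(spec, path)
  back <- read_score_spec(path)
  expect_equal(back$max_score, spec$max_score)
  set.seed(96)
  pts <- data.frame(bin = rbinom(30, 1, 0.5), lab = runif(30, 3, 10),
                    thr = runif(30, 0, 100))
  expect_identical(apply_score(back, pts), apply_score(spec, pts))
})
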