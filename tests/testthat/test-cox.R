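test_that("Cox estimate matches the grid-search maximizer of the Breslow likelihood", {
  time <- c(1, 3, 5, 2, 4, 6)
  event <- rep(1L, 6)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- fit_cox(toy_outcomes(time, event), data.frame(x = x))
  beta_grid <- grid_max_breslow(time, event, x)
  expect_lt(abs(fit$coef[1] - beta_grid), 1e-3)

  # the maximized partial likelihood is at least the null value
  expect_gte(attr(fit, "loglik"), attr(fit, "loglik_null"))
})

test_that("relabelling the group indicator flips the coefficient sign", {
  time <- c(1, 3, 5, 2, 4, 6)
  out <- toy_outcomes(time, rep(1L, 6))
  x <- c(1, 1, 1, 0, 0, 0)
  f1 <- fit_cox(out, data.frame(x = x))
  f2 <- fit_cox(out, data.frame(x = 1 - x))
  expect_equal(f1$coef[1], -f2$coef[1], tolerance = 1e-8)
})

test_that("small-sample estimates match direct maximization of the risk-set product", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    time <- sample(1:50, n)  # distinct times
    event <- rbinom(n, 1, 0.8)
    if (sum(event) == 0) event[1] <- 1L
    x <- round(rnorm(n), 2)
    fit <- fit_cox(toy_outcomes(time, event), data.frame(x = x))
    opt <- optimize(function(b) breslow_loglik(b, time, event, x),
                    interval = c(-5, 5), maximum = TRUE)
    expect_lt(abs(fit$coef[1] - opt$maximum), 1e-4)
  }
})

test_that("duplicating every row leaves the estimate unchanged", {
  set.seed(12)
  n <- 40
  time <- sample(1:200, n)
  event <- rbinom(n, 1, 0.6)
  x <- rnorm(n)
  f1 <- fit_cox(toy_outcomes(time, event), data.frame(x = x))
  idx <- rep(seq_len(n), 2)
  f2 <- fit_cox(toy_outcomes(time[idx], event[idx]), data.frame(x = x[idx]))
  expect_equal(f1$coef[1], f2$coef[1], tolerance = 1e-6)
})

test_that("likelihood at the estimate dominates the null across random data", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 60
    time <- sample(1:500, n, replace = TRUE)
    event <- rbinom(n, 1, 0.5)
    if (sum(event) == 0) event[1] <- 1L
    X <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.4))
    if (length(unique(X$b)) < 2) X$b[1] <- 1 - X$b[1]
    fit <- fit_cox(toy_outcomes(time, event), X)
    expect_gte(attr(fit, "loglik"), attr(fit, "loglik_null") - 1e-10)
  }
})

test_that("degenerate inputs produce named errors and missing rows are dropped", {
  out <- toy_outcomes(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_error(fit_cox(out, data.frame(flat = rep(1, 4))), "flat")
  expect_error(fit_cox(toy_outcomes(1:4, rep(0L, 4)), data.frame(x = rnorm(4))),
               "no events")

  X <- data.frame(x = c(0.3, NA, -0.2, 1.1))
  fit <- fit_cox(out, X)
  expect_equal(attr(fit, "n_dropped"), 1L)
  expect_equal(attr(fit, "n_used"), 3L)

  # HR and CI are consistent transforms of the coefficient
  expect_equal(fit$hr, exp(fit$coef))
  expect_true(all(fit$lower <= fit$hr & fit$hr <= fit$upper))
})

test_that("the univariate screen retains exactly the candidates below alpha", {
  set.seed(14)
  n <- 600
  x_true <- rbinom(n, 1, 0.5)
  x_null <- rnorm(n)
  time <- rexp(n, rate = 0.05 * exp(log(2.5) * x_true))
  event <- as.integer(time < 15)
  time <- pmin(time, 15)
  out <- toy_outcomes(round(time * 365.25), event)
  X <- data.frame(x_true = x_true, x_null = x_null, flat = 1)

  retained <- suppressWarnings(univariate_screen(out, X, alpha = 0.10))
  res <- attr(retained, "results")
  expect_setequal(as.character(retained), res$term[res$p < 0.10])
  expect_true("x_true" %in% retained)
  expect_false("flat" %in% res$term)  # degenerate candidate skipped
  expect_warning(univariate_screen(out, X, alpha = 0.10), "flat")
})

test_that("the joint model is pruned once and refitted on the survivors", {
  set.seed(15)
  n <- 2000
  x1 <- rbinom(n, 1, 0.5)   # real effect
  x2 <- rnorm(n)            # null
  time <- rexp(n, rate = 0.08 * exp(log(2) * x1))
  event <- as.integer(time < 12)
  out <- toy_outcomes(round(pmin(time, 12) * 365.25), event)
  X <- data.frame(x1 = x1, x2 = x2)

  refit <- multivariate_refit(out, X, screened = c("x1", "x2"), alpha = 0.05)
  joint <- attr(refit, "joint")
  expect_equal(nrow(joint), 2L)
  kept <- joint$term[joint$p < 0.05]
  expect_setequal(refit$term, kept)

  # fixed point: when everything is significant the joint fit is reused
  refit1 <- multivariate_refit(out, X, screened = "x1", alpha = 0.05)
  expect_equal(refit1$coef, attr(refit1, "joint")$coef)

  # nothing significant -> empty model with a warning
  expect_warning(
    empty <- multivariate_refit(out, X, screened = "x2", alpha = 1e-6),
    "empty score model")
  expect_equal(nrow(empty), 0L)
  expect_error(multivariate_refit(out, X, screened = character(0)), "empty")
})

test_that("selection recovers true actives with controlled false inclusion", {
  # 3 true effects + 5 null covariates, n = 20,000 per replicate. Exact
  # set recovery cannot exceed the (1 - alpha)^5 ceiling implied by five
  # independent null covariates tested at alpha = 0.05, so power and
  # type-I behaviour are checked separately.
  n_rep <- 60
  n <- 20000
  beta <- c(a = log(1.4), b = log(1.3), c = log(0.75))
  all_true <- 0L
  null_kept <- 0L
  set.seed(16)
  for (r in seq_len(n_rep)) {
    X <- data.frame(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.3),
                    c = rbinom(n, 1, 0.5), n1 = rnorm(n), n2 = rbinom(n, 1, 0.2),
                    n3 = rnorm(n), n4 = rbinom(n, 1, 0.5), n5 = rnorm(n))
    lp <- beta["a"] * X$a + beta["b"] * X$b + beta["c"] * X$c
    t_ev <- rexp(n, rate = 0.008 * exp(lp))
    event <- as.integer(t_ev < 11)
    out <- toy_outcomes(round(pmin(t_ev, 11) * 365.25), event)
    refit <- multivariate_refit(out, X, screened = names(X), alpha = 0.05)
    if (all(c("a", "b", "c") %in% refit$term)) all_true <- all_true + 1L
    null_kept <- null_kept + length(setdiff(refit$term, c("a", "b", "c")))
  }
  expect_gte(all_true / n_rep, 0.90)            # power on the true actives
  expect_lte(null_kept / (5 * n_rep), 0.10)     # per-null inclusion near alpha
})
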