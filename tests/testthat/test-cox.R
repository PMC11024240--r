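test_that("negative log partial likelihood reproduces hand-computed values", {
  # all-zero scores reduce to log risk-set sizes
  expect_equal(negative_log_partial_likelihood(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1)),
               log(6), tolerance = 1e-12)
  # singleton risk set
  expect_equal(negative_log_partial_likelihood(5, 4, 1), 0)
  # two subjects, direct evaluation
  expect_equal(negative_log_partial_likelihood(c(1, 0), c(1, 2), c(1, 1)),
               log(exp(1) + 1) - 1, tolerance = 1e-12)
  # Breslow ties: both events at t = 1 share the full-risk-set denominator
  expect_equal(negative_log_partial_likelihood(c(0, 0), c(1, 1), c(1, 1)),
               2 * log(2), tolerance = 1e-12)
})

test_that("partial likelihood is invariant to score shifts and rejects bad input", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    s <- rnorm(n); t <- rexp(n, 0.1) + 0.01
    e <- rbinom(n, 1, 0.7); if (sum(e) == 0) e[1] <- 1
    base <- negative_log_partial_likelihood(s, t, e)
    shift <- negative_log_partial_likelihood(s + runif(1, -50, 50), t, e)
    expect_lt(abs(base - shift), 1e-10)
  }
  expect_error(negative_log_partial_likelihood(c(0, 0), c(1, 2), c(0, 0)),
               "no-events")
  expect_error(negative_log_partial_likelihood(c(NaN, 0), c(1, 2), c(1, 1)),
               "invalid-score")
  expect_error(negative_log_partial_likelihood(c(Inf, 0), c(1, 2), c(1, 1)),
               "invalid-score")
})

test_that("deepsurv loss scales by event count and adds the penalty linearly", {
  s <- c(0.4, -1, 2, 0); t <- c(2, 5, 1, 3); e <- c(1, 0, 1, 1)
  expect_equal(deepsurv_loss(s, t, e),
               negative_log_partial_likelihood(s, t, e) / 3)
  expect_equal(deepsurv_loss(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1)), log(6) / 3)
  expect_equal(deepsurv_loss(s, t, e, weight_sq_norm = 2, lambda = 0.5) -
                 deepsurv_loss(s, t, e), 1.0)
})

test_that("Newton Cox fit matches the survival package on random instances", {
  skip_if_not_installed("survival")
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(40:120, 1)
    p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n, p)
    beta <- runif(p, -1, 1)
    t0 <- rexp(n, 0.1 * exp(drop(x %*% beta)))
    c0 <- runif(n, 0, 25)
    tt <- pmin(t0, c0); ee <- as.integer(t0 <= c0)
    if (sum(ee) < 5) next
    fit <- fit_linear_cox(x, tt, ee)
    ref <- survival::coxph(survival::Surv(tt, ee) ~ x, ties = "breslow")
    expect_lt(max(abs(fit$beta - unname(coef(ref)))), 1e-6)
    expect_lt(max(abs(fit$standard_errors -
                        unname(sqrt(diag(vcov(ref)))))), 1e-6)
    expect_equal(fit$log_likelihood, ref$loglik[2], tolerance = 1e-8)
  }
})

test_that("Newton Cox fit recovers a known effect and detects a null one", {
  d <- sim_ph_data(500, beta = 0.8, seed = 11)
  fit <- fit_linear_cox(matrix(d$x), d$time, d$event)
  expect_lt(abs(fit$beta - 0.8), 0.15)
  ci <- fit$beta + c(-1.96, 1.96) * fit$standard_errors
  expect_true(ci[1] < 0.8 && 0.8 < ci[2])

  set.seed(5)
  g <- rbinom(600, 1, 0.5)
  t0 <- rexp(600, 0.1)          # identical distribution in both groups
  fit0 <- fit_linear_cox(matrix(g), t0, rep(1, 600))
  expect_lt(abs(fit0$beta), 2 * fit0$standard_errors)
})

test_that("Cox fit errors are informative", {
  expect_error(fit_linear_cox(matrix(rep(1, 10)), 1:10, rep(1, 10)),
               "constant-covariate")
  expect_error(fit_linear_cox(matrix(rnorm(10)), 1:10, rep(0, 10)),
               "no-events")
  # complete separation: every group-1 event precedes all group-0 follow-up
  x <- c(rep(1, 5), rep(0, 5))
  tt <- c(1:5, 101:105)
  ee <- rep(1, 10)
  expect_error(fit_linear_cox(matrix(x), tt, ee), "divergent-beta")
})

test_that("Breslow baseline hazard matches hand computation and its shift identity", {
  b <- breslow_cumulative_hazard(c(0, 0), c(1, 2), c(1, 1))
  expect_equal(b$cumulative_hazard, c(1 / 2, 3 / 2))
  set.seed(3)
  s <- rnorm(30); t <- rexp(30, 0.1) + 0.01; e <- rbinom(30, 1, 0.6)
  e[1] <- 1
  b0 <- breslow_cumulative_hazard(s, t, e)
  b1 <- breslow_cumulative_hazard(s + 2, t, e)
  expect_equal(b1$cumulative_hazard, b0$cumulative_hazard * exp(-2),
               tolerance = 1e-12)
})

test_that("Breslow with null scores approaches the true cumulative hazard", {
  set.seed(9)
  n <- 2000; lambda0 <- 0.1
  t <- rexp(n, lambda0)
  b <- breslow_cumulative_hazard(rep(0, n), t, rep(1, n))
  for (tt in c(2, 5, 10))
    expect_lt(abs(cumulative_hazard_at(b, tt) - lambda0 * tt) / (lambda0 * tt),
              0.06)
  # Nelson-Aalen vs product-limit agreement at n = 500
  set.seed(10)
  t <- rexp(500, 0.08); c0 <- runif(500, 0, 30)
  tt <- pmin(t, c0); ee <- as.integer(t <= c0)
  b <- breslow_cumulative_hazard(rep(0, 500), tt, ee)
  km <- kaplan_meier(tt, ee)
  expect_lt(max(abs(exp(-b$cumulative_hazard) - km$surv)), 0.02)
})

test_that("predicted event probability behaves as a distribution function", {
  curve0 <- structure(list(times = 5, cumulative_hazard = log(2)),
                      class = "baseline_hazard")
  expect_equal(predicted_event_probability(0, curve0, 2), 0)       # before 1st event
  expect_equal(predicted_event_probability(0, curve0, 6), 0.5)     # closed form
  set.seed(12)
  s <- rnorm(50); t <- rexp(50, 0.1); e <- rbinom(50, 1, 0.8); e[1] <- 1
  b <- breslow_cumulative_hazard(s, t, e)
  p12 <- predicted_event_probability(s, b, 12)
  p24 <- predicted_event_probability(s, b, 24)
  expect_true(all(p24 >= p12))
  expect_true(all(p12 >= 0 & p24 <= 1))
  # monotone in the score
  grid <- seq(-3, 3, by = 0.5)
  expect_true(!is.unsorted(predicted_event_probability(grid, b, 12)))
  expect_error(predicted_event_probability(0, b, -1), "invalid-horizon")
})

test_that("Kaplan-Meier estimator matches the reference implementation", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km_at(kaplan_meier(c(1, 2), c(0, 0)), c(0.5, 5)), c(1, 1))
  skip_if_not_installed("survival")
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(20:80, 1)
    t <- round(rexp(n, 0.1), 1) + 0.1      # induces ties
    e <- rbinom(n, 1, 0.6)
    km <- kaplan_meier(t, e)
    if (length(km$times) == 0) next
    sf <- summary(survival::survfit(survival::Surv(t, e) ~ 1), times = km$times)
    expect_equal(km$surv, sf$surv, tolerance = 1e-12)
  }
})

test_that("km_at honours right continuity and left limits", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km_at(km, c(0.5, 1, 1.5, 2)), c(1, 2 / 3, 2 / 3, 1 / 3))
  expect_equal(km_at(km, c(1, 2), left = TRUE), c(1, 2 / 3))
})
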