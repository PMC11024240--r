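test_that("risk-group assignment applies the documented tie rule", {
  expect_equal(as.character(assign_risk_groups(c(0.2, 0.8))), c("low", "high"))
  expect_true(all(assign_risk_groups(rep(0.5, 4)) == "low"))
  g <- assign_risk_groups(runif(57))
  expect_equal(sum(table(g)), 57)
  expect_error(assign_risk_groups(numeric(0)), "empty-input")
  expect_error(assign_risk_groups(c(0.2, 1.4)), "invalid-probability")
})

test_that("ART hazard ratio recovers null and non-null effects", {
  set.seed(61)
  n <- 400
  art <- rbinom(n, 1, 0.5)
  t_null <- rexp(n, 0.08)                     # identical arms
  r0 <- art_benefit_hr(t_null, rep(1, n), art)
  expect_true(r0$hr > 0.8 && r0$hr < 1.25)
  expect_gt(r0$p, 0.05)

  set.seed(62)
  n <- 300
  art <- rbinom(n, 1, 0.5)
  t3 <- rexp(n, 0.05 * ifelse(art == 1, 3, 1))
  cens <- pmin(rexp(n, 0.02), 48)
  r3 <- art_benefit_hr(pmin(t3, cens), as.integer(t3 <= cens), art)
  expect_true(r3$ci_low < 3 && 3 < r3$ci_high)
  expect_lt(r3$p, 0.05)
  # label swap inverts the hazard ratio exactly
  rswap <- art_benefit_hr(pmin(t3, cens), as.integer(t3 <= cens), 1 - art)
  expect_equal(rswap$hr, 1 / r3$hr, tolerance = 1e-8)
  expect_equal(rswap$p, r3$p, tolerance = 1e-8)
})

test_that("single-arm strata and separation are surfaced, not silently fit", {
  expect_error(art_benefit_hr(rexp(10, 0.1), rep(1, 10), rep(1, 10)),
               "no-contrast")
  # separation: every ART event precedes all non-ART follow-up
  tt <- c(1:5, 101:105)
  art <- c(rep(1, 5), rep(0, 5))
  r <- art_benefit_hr(tt, rep(1, 10), art)
  expect_true(r$separation)
  expect_true(is.na(r$hr))
})

test_that("the time-dependent convention also recovers the treatment effect", {
  set.seed(63)
  n <- 800
  r0 <- 0.03; hr <- 3; t_start <- 12
  u <- -log(runif(n))
  eligible <- u > r0 * t_start
  art <- eligible & runif(n) < 0.5
  tt <- ifelse(art, t_start + (u - r0 * t_start) / (r0 * hr), u / r0)
  cens <- pmin(48, rexp(n, 0.01))
  time <- pmin(tt, cens); ev <- as.integer(tt <= cens)
  r_td <- art_benefit_hr(time, ev, as.integer(art), time_dependent = TRUE,
                         art_start_month = t_start)
  expect_true(r_td$ci_low < hr && hr < r_td$ci_high)
})

test_that("the stratification table recovers a benefit concentrated in the low stratum", {
  cfg <- strat_config(seed = 71, n = 600, art_low = 3, art_high = 1)
  coh <- generate_cohort(cfg, render = FALSE)
  rec <- coh$records
  # the time-dependent convention puts ART patients in the treated risk set
  # only from ART initiation, so the benefit is recoverable
  tab <- stratification_table(rec, coh$truth$true_p_conception_1yr,
                              stratifiers = "model", time_dependent = TRUE)
  expect_equal(nrow(tab), 2)
  expect_equal(sum(tab$n), 600)
  low <- tab[tab$stratum_label == "<0.5", ]
  high <- tab[tab$stratum_label == ">0.5", ]
  expect_gt(low$hr, 1)
  expect_lt(low$p, 0.05)
  expect_true(high$ci_low < 1 && 1 < high$ci_high)
  # the baseline-covariate reading counts the pre-ART event-free months as
  # treated exposure (immortal time) and must therefore be biased downward
  naive <- stratification_table(rec, coh$truth$true_p_conception_1yr,
                                stratifiers = "model", time_dependent = FALSE)
  expect_lt(naive$hr[naive$stratum_label == "<0.5"], low$hr)
})

test_that("clinical comparator strata partition the cohort", {
  cfg <- strat_config(seed = 73, n = 400)
  coh <- generate_cohort(cfg, render = FALSE)
  rec <- coh$records
  tab <- stratification_table(rec, coh$truth$true_p_conception_1yr)
  expect_equal(nrow(tab), 8)                       # 4 stratifiers x 2 strata
  for (s in unique(tab$stratifier))
    expect_equal(sum(tab$n[tab$stratifier == s]), 400)
})

test_that("confidence intervals for the stratum hazard ratio have near-nominal coverage", {
  set.seed(80)
  covered <- 0; reps <- 200
  for (r in seq_len(reps)) {
    n <- 300
    art <- rbinom(n, 1, 0.5)
    t3 <- rexp(n, 0.05 * ifelse(art == 1, 3, 1))
    cens <- pmin(rexp(n, 0.02), 48)
    rep_r <- art_benefit_hr(pmin(t3, cens), as.integer(t3 <= cens), art)
    if (rep_r$ci_low < 3 && 3 < rep_r$ci_high) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.90)
  expect_lte(covered / reps, 0.99)
})
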