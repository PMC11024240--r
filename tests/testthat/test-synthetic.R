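test_that("rendered images are deterministic and severity-monotone", {
  cfg <- generator_config(n_patients = 1, image_size = 48, seed = 3)
  a <- render_image(0.7, "cavity", cfg, seed = 101)
  b <- render_image(0.7, "cavity", cfg, seed = 101)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_equal(sum(render_image(0, "cavity", cfg, seed = 5)$mask), 0)
  s0 <- sum(render_image(0.2, "cavity", cfg, seed = 7)$mask)
  s1 <- sum(render_image(1.0, "cavity", cfg, seed = 7)$mask)
  expect_gt(s1, s0)
  expect_gt(s0, 0)
  cor1 <- render_image(0.8, "left_cornu", cfg, seed = 9)
  expect_gt(sum(cor1$mask), 0)
  expect_true(all(a$image >= 0 & a$image <= 1))
})

test_that("event rate matches the closed-form exponential probability", {
  cfg <- generator_config(n_patients = 1000, beta_severity = -1.2,
                          loss_to_followup_rate = 0, art_probability = 0,
                          seed = 17)
  coh <- generate_cohort(cfg, render = FALSE)
  # P(T <= 48) integrated over severity ~ U(0, 1)
  p_event <- stats::integrate(function(s)
    1 - exp(-cfg$baseline_rate * exp(cfg$beta_severity * (s - 0.5)) * 48),
    0, 1)$value
  phat <- mean(coh$records$event)
  expect_lt(abs(phat - p_event), 3 * sqrt(p_event * (1 - p_event) / 1000))
})

test_that("severity carries no signal when its coefficient is zero", {
  cfg <- generator_config(n_patients = 400, beta_severity = 0, seed = 19,
                          art_probability = 0)
  coh <- generate_cohort(cfg, render = FALSE)
  ci <- harrell_cindex(-coh$truth$severity, coh$records$time_months,
                       coh$records$event, B = 0)
  expect_lt(abs(ci$c_index - 0.5), 0.06)
})

test_that("the oracle Cox fit recovers the generating coefficient", {
  cfg <- generator_config(n_patients = 500, beta_severity = -2, seed = 23,
                          art_probability = 0)
  coh <- generate_cohort(cfg, render = FALSE)
  fit <- fit_linear_cox(matrix(coh$truth$severity), coh$records$time_months,
                        coh$records$event)
  expect_lt(abs(fit$beta - (-2)), 0.5)
  ci <- fit$beta + c(-1.96, 1.96) * fit$standard_errors
  expect_true(ci[1] < -2 && -2 < ci[2])
  # generator honesty: bias well under 10% of |beta| at n = 2000
  cfg2 <- generator_config(n_patients = 2000, beta_severity = -1.2, seed = 29,
                           art_probability = 0)
  coh2 <- generate_cohort(cfg2, render = FALSE)
  fit2 <- fit_linear_cox(matrix(coh2$truth$severity),
                         coh2$records$time_months, coh2$records$event)
  expect_lt(abs(fit2$beta - (-1.2)), 0.1 * 1.2 + 1.96 * fit2$standard_errors)
})

test_that("patient-level splits follow the 3:1 then 8:2 design", {
  ids <- sprintf("P%03d", 1:100)
  sp <- make_splits(ids, seed = 4)
  expect_equal(lengths(sp[c("train", "validation", "test")]),
               c(train = 60, validation = 15, test = 25))
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(intersect(sp$validation, sp$test), 0)
  expect_identical(sp, make_splits(ids, seed = 4))
  expect_false(identical(sp, make_splits(ids, seed = 5)))
  expect_error(make_splits(ids[1:2], seed = 1), "cohort-too-small")
})

test_that("generated cohorts respect their configuration invariants", {
  expect_error(generator_config(n_patients = 10), "missing-seed")
  cfg <- generator_config(n_patients = 20, images_per_patient = 3,
                          image_size = 24, seed = 31)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$records), 20)
  expect_false(anyDuplicated(coh$records$patient_id) > 0)
  expect_true(all(coh$records$time_months > 0))
  expect_true(all(coh$records$event %in% 0:1))
  expect_length(coh$images, 20)
  expect_true(all(lengths(coh$images) == 3))
  # ART only ever starts among patients still at risk at the start month
  started <- coh$records$art == 1
  expect_true(all(coh$truth$no_art_time[started] > cfg$art_start_month))
})
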