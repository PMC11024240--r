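test_that("preprocessing enforces resolution, converts colour, and is deterministic", {
  spec <- backbone_spec("inception_v3")
  small <- array(runif(299 * 400 * 3), c(299, 400, 3))
  expect_error(preprocess_image(small, spec), "below-min-resolution")
  ok <- array(runif(336 * 336 * 3), c(336, 336, 3))
  out <- preprocess_image(ok, spec)
  expect_equal(out, ok * 2 - 1, tolerance = 1e-12)   # identity resize + scaling
  expect_identical(preprocess_image(ok, spec), preprocess_image(ok, spec))
  expect_warning(preprocess_image(matrix(runif(336 * 336), 336, 336), spec),
                 "grayscale")
  big <- array(runif(400 * 380 * 3), c(400, 380, 3))
  expect_equal(dim(preprocess_image(big, spec)), c(336, 336, 3))
})

test_that("patient-level aggregation honours its contract", {
  spec <- backbone_spec("tiny_test", input_size = 16)
  m <- build_model(spec, seed = 6)
  set.seed(6)
  img1 <- array(runif(16 * 16 * 3), c(16, 16, 3))
  img2 <- array(runif(16 * 16 * 3) * 0.2, c(16, 16, 3))
  one <- predict_patient(m, list(img1))
  dup <- predict_patient(m, list(img1, img1, img1))
  expect_equal(one$log_hazard, dup$log_hazard)
  pair_mean <- predict_patient(m, list(img1, img2), aggregation = "mean")
  pair_max <- predict_patient(m, list(img1, img2), aggregation = "max")
  expect_equal(pair_max$log_hazard, max(pair_mean$per_image))
  expect_equal(pair_mean$log_hazard, mean(pair_mean$per_image))
  expect_gte(pair_max$log_hazard, pair_mean$log_hazard)
  expect_error(predict_patient(m, list()), "no-images")
})

test_that("training reduces the Cox loss on a learnable cohort", {
  cfg <- generator_config(n_patients = 40, image_size = 24,
                          beta_severity = -8, seed = 41)
  coh <- generate_cohort(cfg)
  spec <- backbone_spec("tiny_test", input_size = 24, tiny_channels = c(6, 8))
  pre <- lapply(coh$images, function(im)
    lapply(im, function(x) preprocess_image(x, spec)))
  flat <- unlist(pre, recursive = FALSE)
  tt <- rep(coh$records$time_months, each = 3)
  ee <- rep(coh$records$event, each = 3)
  m <- build_model(spec, seed = 41)
  trained <- train_deepsurv(m, flat, tt, ee,
                            train_config(learning_rate = 0.02, epochs = 6,
                                         weight_decay = 1e-4, seed = 41))
  h <- attr(trained, "history")
  expect_lt(min(h$train_loss), h$train_loss[1])
  expect_equal(nrow(h), 6)
})

test_that("a large weight-decay penalty shrinks the weights", {
  set.seed(44)
  n <- 40
  x <- matrix(rnorm(n * 3), n, 3)
  tt <- rexp(n, 0.1) + 0.1; ee <- rbinom(n, 1, 0.8); ee[1:2] <- 1
  ns <- asNamespace("hysterosurv")
  norm_after <- function(lambda) {
    m <- build_tabular_model(3, survival_head_spec(hidden_layers = 1,
                                                   dropout = 0,
                                                   batch_norm = FALSE),
                             seed = 44)
    m <- train_deepsurv(m, x, tt, ee,
                        train_config(learning_rate = 0.01, weight_decay = lambda,
                                     epochs = 100, batch_size = n, seed = 44))
    ns$net_weight_sq_norm(m)
  }
  expect_lt(norm_after(1000), 0.25 * norm_after(0))
})

test_that("a linear head trained to convergence matches the Newton Cox oracle", {
  d <- sim_ph_data(500, beta = 0.8, seed = 47)
  x <- cbind(d$x, rnorm(500, sd = 0.5))
  fit <- fit_linear_cox(x, d$time, d$event)
  m <- build_tabular_model(2, survival_head_spec(hidden_layers = 0, dropout = 0,
                                                 batch_norm = FALSE), seed = 1)
  m <- train_deepsurv(m, x, d$time, d$event,
                      train_config(learning_rate = 0.05, weight_decay = 0,
                                   epochs = 400, batch_size = 500, seed = 1,
                                   gradient_clip = Inf))
  sc <- drop(asNamespace("hysterosurv")$net_forward(m, x)$out)
  sc_oracle <- drop(x %*% fit$beta)
  c_nn <- harrell_cindex(sc, d$time, d$event, B = 0)$c_index
  c_or <- harrell_cindex(sc_oracle, d$time, d$event, B = 0)$c_index
  expect_lt(abs(c_nn - c_or), 0.02)
  # pairwise score differences agree, not just the ranking
  idx <- sample(500, 50)
  expect_lt(max(abs(outer(sc[idx], sc[idx], "-") -
                      outer(sc_oracle[idx], sc_oracle[idx], "-"))), 0.05)
})

test_that("training is reproducible and guards its preconditions", {
  set.seed(50)
  n <- 30
  x <- matrix(rnorm(n * 2), n, 2)
  tt <- rexp(n, 0.1) + 0.1; ee <- rbinom(n, 1, 0.7); ee[1:2] <- 1
  run <- function() {
    m <- build_tabular_model(2, survival_head_spec(hidden_layers = 1,
                                                   dropout = 0.3,
                                                   batch_norm = TRUE), seed = 2)
    m <- train_deepsurv(m, x, tt, ee,
                        train_config(learning_rate = 0.01, epochs = 4,
                                     batch_size = 8, seed = 2))
    list(h = attr(m, "history"), w = m$layers[[1]]$params$W)
  }
  a <- run(); b <- run()
  expect_identical(a$h, b$h)
  expect_identical(a$w, b$w)
  expect_error(train_deepsurv(build_tabular_model(2, seed = 1), x, tt,
                              rep(0, n), train_config(seed = 1)), "no-events")
  expect_error(build_model(backbone_spec("resnet50")), "untrainable-backbone")
})

test_that("inference timing returns positive seconds and lands in the report", {
  spec <- backbone_spec("tiny_test", input_size = 16)
  t1 <- measure_inference_time(build_model(spec, seed = 1), n_images = 2,
                               repeats = 2)
  expect_gte(t1, 0)
  rep <- complexity_report(spec, measure_time = TRUE)
  expect_true(is.finite(rep$avg_inference_seconds))
})
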