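#' Synthetic-cohort generator configuration
#'
#' Defines the data-generating law for a hysteroscopy-like cohort: per-patient
#' adhesion severity drives both the rendered images and the conception
#' hazard under a proportional-hazards model with right censoring and an
#' ART treatment effect switched on at `art_start_month` for a random half of
#' the still-unconceived patients.
#'
#' Event times follow a Weibull law with cumulative hazard
#' `H(t) = rate_i * t^shape` (exponential when `shape = 1`), where
#' `rate_i = baseline_rate * exp(beta_severity * (severity_i - 0.5))` and
#' `severity_i ~ Uniform(0, 1)`. Worse adhesions (higher severity) lower the
#' conception hazard via the negative default `beta_severity`. From
#' `art_start_month` the hazard of ART starters is multiplied by the
#' stratum-appropriate hazard ratio: the stratum is the patient's true
#' 1-year conception probability below/above 0.5, mirroring the benefit
#' pattern the stratification module is meant to recover.
#'
#' @param n_patients cohort size.
#' @param images_per_patient images per patient (default 3: one cavity and
#'   two cornua views).
#' @param image_size image side in pixels.
#' @param beta_severity true log-hazard coefficient of centered severity.
#' @param baseline_rate events/month for the median (severity 0.5) patient.
#' @param admin_censor_months administrative censoring time.
#' @param loss_to_followup_rate exponential dropout rate (events/month).
#' @param art_start_month month at which ART can begin.
#' @param art_probability probability that an eligible patient starts ART.
#' @param art_hr_low_stratum,art_hr_high_stratum true ART hazard ratios in
#'   the low/high 1-year-probability strata.
#' @param weibull_shape Weibull shape (1 = exponential).
#' @param seed mandatory integer seed.
#' @export
generator_config <- function(n_patients, images_per_patient = 3,
                             image_size = 48, beta_severity = -1.2,
                             baseline_rate = 0.012, admin_censor_months = 48,
                             loss_to_followup_rate = 0.003,
                             art_start_month = 12, art_probability = 0.5,
                             art_hr_low_stratum = 3.13,
                             art_hr_high_stratum = 0.52,
                             weibull_shape = 1, seed) {
  if (missing(seed)) hs_error("missing-seed", "generator seed is mandatory")
  stopifnot(n_patients >= 1, images_per_patient >= 1, image_size >= 16,
            baseline_rate > 0, admin_censor_months > 0,
            loss_to_followup_rate >= 0, art_start_month > 0,
            art_hr_low_stratum > 0, art_hr_high_stratum > 0, weibull_shape > 0)
  structure(as.list(environment()), class = "generator_config")
}

#' Render one synthetic hysteroscopic view
#'
#' A pale elliptical cavity on a dark background. The cavity view shows
#' `ceiling(severity * 4)` dark occluding adhesion bands whose thickness also
#' grows with severity; the cornua views show an ostium disc whose opening is
#' occluded proportionally to severity. Gaussian noise and an illumination
#' gradient are added. Deterministic given `(severity, view, seed)`.
#'
#' @param severity adhesion severity in `[0, 1]`.
#' @param view `"cavity"`, `"left_cornu"` or `"right_cornu"`.
#' @param config a [generator_config()].
#' @param seed rendering seed.
#' @return list: `image` (`S x S x 3` array in `[0, 1]`) and `mask`
#'   (`S x S` 0/1 matrix of adhesion pixels).
#' @export
render_image <- function(severity, view = c("cavity", "left_cornu", "right_cornu"),
                         config, seed) {
  view <- match.arg(view)
  stopifnot(severity >= 0, severity <= 1)
  S <- config$image_size
  with_local_seed(seed, {
    yy <- matrix(seq_len(S), S, S)
    xx <- matrix(seq_len(S), S, S, byrow = TRUE)
    cx <- S / 2 + stats::runif(1, -S * 0.03, S * 0.03)
    cy <- S / 2 + stats::runif(1, -S * 0.03, S * 0.03)
    img <- array(0.12, c(S, S, 3))
    mask <- matrix(0, S, S)
    if (view == "cavity") {
      rx <- S * 0.38; ryl <- S * 0.32
      inside <- ((xx - cx) / rx)^2 + ((yy - cy) / ryl)^2 <= 1
      base <- c(0.85, 0.62, 0.60)
      for (ch in 1:3) { p <- img[, , ch]; p[inside] <- base[ch]; img[, , ch] <- p }
      n_bands <- ceiling(severity * 4)
      if (n_bands > 0) {
        thick <- max(1, round(S * 0.02 * (1 + 2 * severity)))
        ys <- round(stats::runif(n_bands, cy - ryl * 0.8, cy + ryl * 0.8))
        for (y0 in ys) {
          rows <- pmin(pmax(y0:(y0 + thick - 1), 1), S)
          band <- matrix(FALSE, S, S)
          band[rows, ] <- TRUE
          band <- band & inside
          for (ch in 1:3) { p <- img[, , ch]; p[band] <- c(0.35, 0.22, 0.22)[ch]; img[, , ch] <- p }
          mask[band] <- 1
        }
      }
    } else {
      r_disc <- S * 0.30
      inside <- sqrt((xx - cx)^2 + (yy - cy)^2) <= r_disc
      base <- c(0.80, 0.58, 0.56)
      for (ch in 1:3) { p <- img[, , ch]; p[inside] <- base[ch]; img[, , ch] <- p }
      # dark ostium opening, partially occluded by pale scar tissue
      r_ost <- S * 0.10
      ost <- sqrt((xx - cx)^2 + (yy - cy)^2) <= r_ost
      for (ch in 1:3) { p <- img[, , ch]; p[ost] <- 0.10; img[, , ch] <- p }
      if (severity > 0) {
        ang <- atan2(yy - cy, xx - cx)
        a0 <- stats::runif(1, -pi, pi)
        width <- severity * 2 * pi
        dd <- (ang - a0) %% (2 * pi)
        occ <- ost & dd <= width
        for (ch in 1:3) { p <- img[, , ch]; p[occ] <- c(0.38, 0.25, 0.25)[ch]; img[, , ch] <- p }
        mask[occ] <- 1
      }
    }
    grad <- outer(seq(-0.05, 0.05, length.out = S),
                  seq(-0.05, 0.05, length.out = S), `+`) / 2
    noise <- array(stats::rnorm(S * S * 3, 0, 0.02), c(S, S, 3))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + grad
    img <- pmin(pmax(img + noise, 0), 1)
    list(image = img, mask = mask)
  })
}

# inverse of the piecewise cumulative hazard with an ART multiplier from t0
invert_cumhaz <- function(u_neg_log, rate, shape, art, t0, hr) {
  h1 <- function(t) rate * t^shape
  if (!art) return((u_neg_log / rate)^(1 / shape))
  h_t0 <- h1(t0)
  if (u_neg_log <= h_t0) return((u_neg_log / rate)^(1 / shape))
  (((u_neg_log - h_t0) / hr + h_t0) / rate)^(1 / shape)
}

#' Generate a synthetic cohort
#'
#' Draws per-patient severities, event and censoring times under the law of
#' [generator_config()], renders the images, and returns the cohort plus a
#' ground-truth table. When `dir` is given, writes `cohort.csv`, `truth.csv`
#' and `images/<patient_id>/<view>.png`.
#'
#' @param config a [generator_config()].
#' @param dir optional output directory.
#' @param render render images (set `FALSE` for outcome-only studies, e.g.
#'   large parameter-recovery simulations).
#' @return object of class `synthetic_cohort`: `records` (data frame:
#'   patient_id, time_months, event, art, age, afs, csge, emt_mm),
#'   `images` (named list of per-patient image lists), `masks`, `truth`
#'   (severity, true rate, counterfactual times), `config`.
#' @export
generate_cohort <- function(config, dir = NULL, render = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  views <- c("cavity", "left_cornu", "right_cornu")
  out <- with_local_seed(config$seed, {
    severity <- stats::runif(n)
    rate <- config$baseline_rate * exp(config$beta_severity * (severity - 0.5))
    p1yr <- 1 - exp(-rate * 12^config$weibull_shape)
    stratum_low <- p1yr < 0.5
    hr <- ifelse(stratum_low, config$art_hr_low_stratum, config$art_hr_high_stratum)
    u <- -log(stats::runif(n))
    t_pre <- (u / rate)^(1 / config$weibull_shape)   # no-ART counterfactual
    cens <- pmin(config$admin_censor_months,
                 if (config$loss_to_followup_rate > 0)
                   stats::rexp(n, config$loss_to_followup_rate) else Inf)
    eligible <- t_pre > config$art_start_month & cens > config$art_start_month
    art <- eligible & stats::runif(n) < config$art_probability
    t_event <- vapply(seq_len(n), function(i)
      invert_cumhaz(u[i], rate[i], config$weibull_shape, art[i],
                    config$art_start_month, hr[i]), numeric(1))
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
    age <- round(stats::rnorm(n, 32, 4))
    afs <- pmin(12, pmax(1, round(2 + 9 * severity + stats::rnorm(n, 0, 1))))
    csge <- pmin(28, pmax(0, round(4 + 20 * severity + stats::rnorm(n, 0, 2))))
    emt <- round(9 - 3.5 * severity + stats::rnorm(n, 0, 0.8), 1)
    list(severity = severity, rate = rate, p1yr = p1yr, art = art,
         t_event = t_event, cens = cens, time = time, event = event,
         age = age, afs = afs, csge = csge, emt = emt, t_pre = t_pre)
  })
  pid <- sprintf("P%04d", seq_len(n))
  records <- data.frame(
    patient_id = pid,
    time_months = round(out$time, 4),
    event = out$event,
    art = as.integer(out$art),
    age = out$age, afs = out$afs, csge = out$csge, emt_mm = out$emt,
    image_dir = if (is.null(dir)) "" else file.path("images", pid),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    patient_id = pid, severity = out$severity, true_rate = out$rate,
    true_p_conception_1yr = out$p1yr,
    uncensored_time = out$t_event, no_art_time = out$t_pre,
    censoring_time = out$cens, stringsAsFactors = FALSE)
  images <- masks <- NULL
  if (render) {
    images <- masks <- stats::setNames(vector("list", n), pid)
    for (i in seq_len(n)) {
      vs <- views[seq_len(min(config$images_per_patient, 3))]
      if (config$images_per_patient > 3)
        vs <- c(vs, rep("cavity", config$images_per_patient - 3))
      imgs <- list(); mks <- list()
      for (k in seq_along(vs)) {
        sd_k <- derive_seed(config$seed, paste(pid[i], k, vs[k]))
        r <- render_image(out$severity[i], vs[k], config, sd_k)
        imgs[[k]] <- r$image
        mks[[k]] <- r$mask
      }
      images[[i]] <- imgs
      masks[[i]] <- mks
    }
  }
  cohort <- structure(list(records = records, images = images, masks = masks,
                           truth = truth, config = config),
                      class = "synthetic_cohort")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(dir, "cohort.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    if (render) {
      for (i in seq_len(n)) {
        pdir <- file.path(dir, "images", pid[i])
        dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
        for (k in seq_along(images[[i]])) {
          png::writePNG(images[[i]][[k]],
                        file.path(pdir, paste0("view", k, ".png")))
        }
      }
    }
  }
  cohort
}

#' Patient-level train/validation/test splits
#'
#' First holds out a test fraction (default 1/4, the 3:1 modelling/test
#' split), then divides the remainder into training and validation (default
#' 8:2). Splits are by patient, never by image, so no patient's images leak
#' across sets.
#'
#' @param patient_ids character vector (or a `synthetic_cohort`).
#' @param test_fraction fraction held out for external testing.
#' @param validation_fraction fraction of the modelling cohort used for
#'   validation.
#' @param seed split seed.
#' @return list of character vectors `train`, `validation`, `test`.
#' @export
make_splits <- function(patient_ids, test_fraction = 0.25,
                        validation_fraction = 0.2, seed = 1) {
  if (inherits(patient_ids, "synthetic_cohort"))
    patient_ids <- patient_ids$records$patient_id
  n <- length(patient_ids)
  n_test <- round(n * test_fraction)
  n_val <- round((n - n_test) * validation_fraction)
  if (n_test < 1 || n_val < 1 || n - n_test - n_val < 1)
    hs_error("cohort-too-small", "cohort too small for non-empty splits")
  with_local_seed(seed, {
    perm <- sample(patient_ids)
    list(train = sort(perm[seq_len(n - n_test - n_val)]),
         validation = sort(perm[(n - n_test - n_val + 1):(n - n_test)]),
         test = sort(perm[(n - n_test + 1):n]))
  })
}
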