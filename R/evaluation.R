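#' Harrell's concordance index for censored data
#'
#' A pair of patients is usable iff the smaller of the two follow-up times is
#' an event time (tied follow-up times are not usable). A usable pair is
#' concordant when the patient with the shorter event time carries the higher
#' log-hazard score (higher score = higher conception hazard = earlier
#' conception); score ties credit 1/2. The confidence interval is a
#' patient-level percentile bootstrap.
#'
#' @inheritParams negative_log_partial_likelihood
#' @param B number of bootstrap replicates for the CI (0 disables).
#' @param conf_level confidence level.
#' @param seed integer seed for the bootstrap.
#' @return object of class `concordance_result`: `c_index`, `ci_low`,
#'   `ci_high`, `n_concordant`, `n_discordant`, `n_tied_score`.
#' @export
harrell_cindex <- function(scores, times, events, B = 1000,
                           conf_level = 0.95, seed = 1) {
  if (length(scores) != length(times) || length(times) != length(events))
    hs_error("length-mismatch", "equal lengths required")
  counts <- cindex_counts(scores, times, events)
  tot <- counts$conc + counts$disc + counts$tied
  if (tot == 0) hs_error("no-usable-pairs", "no usable pairs for concordance")
  est <- (counts$conc + 0.5 * counts$tied) / tot
  ci <- c(NA_real_, NA_real_)
  if (B > 0) {
    boot <- with_local_seed(seed, {
      n <- length(scores)
      vapply(seq_len(B), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        k <- cindex_counts(scores[idx], times[idx], events[idx])
        d <- k$conc + k$disc + k$tied
        if (d == 0) NA_real_ else (k$conc + 0.5 * k$tied) / d
      }, numeric(1))
    })
    alpha <- 1 - conf_level
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  }
  structure(list(c_index = est, ci_low = ci[1], ci_high = ci[2],
                 n_concordant = counts$conc, n_discordant = counts$disc,
                 n_tied_score = counts$tied),
            class = "concordance_result")
}

# vectorized ordered-pair counts; pair (i, j) counted when t_i < t_j and
# subject i had the event
cindex_counts <- function(scores, times, events) {
  usable <- outer(times, times, "<") & (events == 1)
  sd <- outer(scores, scores, "-")
  list(conc = sum(usable & sd > 0),
       disc = sum(usable & sd < 0),
       tied = sum(usable & sd == 0))
}

#' IPCW time-dependent AUC (cumulative cases / dynamic controls)
#'
#' Discrimination at a fixed horizon between cumulative cases (event by the
#' horizon) and dynamic controls (still event-free past the horizon), with
#' inverse-probability-of-censoring weights from the Kaplan-Meier estimate of
#' the censoring distribution (Uno-style estimator). When no censoring occurs
#' before the horizon all weights are 1 and the statistic reduces exactly to
#' the Mann-Whitney AUC of the binary label `T <= horizon`.
#'
#' @inheritParams harrell_cindex
#' @param horizon positive time (months) within the observed follow-up.
#' @return object of class `time_auc_point`: `horizon`, `auc`, `ci_low`,
#'   `ci_high`, `n_cases`, `n_controls`.
#' @export
ipcw_time_auc <- function(scores, times, events, horizon, B = 1000,
                          conf_level = 0.95, seed = 1) {
  est <- ipcw_auc_point(scores, times, events, horizon)
  ci <- c(NA_real_, NA_real_)
  if (B > 0) {
    boot <- with_local_seed(seed, {
      n <- length(scores)
      vapply(seq_len(B), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(ipcw_auc_point(scores[idx], times[idx], events[idx],
                                horizon)$auc,
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    alpha <- 1 - conf_level
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  }
  structure(list(horizon = horizon, auc = est$auc,
                 ci_low = ci[1], ci_high = ci[2],
                 n_cases = est$n_cases, n_controls = est$n_controls),
            class = "time_auc_point")
}

ipcw_auc_point <- function(scores, times, events, horizon) {
  if (horizon <= 0) hs_error("invalid-horizon", "horizon must be positive")
  case <- times <= horizon & events == 1
  ctrl <- times > horizon
  if (sum(case) == 0 || sum(ctrl) == 0)
    hs_error("degenerate-horizon", "need at least one case and one control at the horizon")
  g <- kaplan_meier(times, 1 - events)       # censoring-distribution KM
  g_case <- km_at(g, times[case], left = TRUE)
  keep <- g_case > 0
  if (!any(keep)) hs_error("degenerate-horizon", "all case weights undefined (G = 0)")
  w <- 1 / g_case[keep]
  sc <- scores[case][keep]
  sj <- scores[ctrl]
  gt <- outer(sc, sj, ">")
  eq <- outer(sc, sj, "==")
  num <- sum(w * (rowSums(gt) + 0.5 * rowSums(eq)))
  den <- sum(w) * length(sj)
  list(auc = num / den, n_cases = sum(case), n_controls = sum(ctrl))
}

#' Time-dependent AUC curve over several horizons
#'
#' @inheritParams ipcw_time_auc
#' @param horizons increasing vector of horizons; horizons that are degenerate
#'   (no cases or no controls) are skipped with a warning.
#' @return list of `time_auc_point` objects, class `time_auc_curve`.
#' @export
time_auc_curve <- function(scores, times, events, horizons, B = 1000,
                           conf_level = 0.95, seed = 1) {
  if (is.unsorted(horizons, strictly = TRUE))
    hs_error("invalid-horizons", "horizons must be strictly increasing")
  pts <- list()
  for (i in seq_along(horizons)) {
    pt <- tryCatch(
      ipcw_time_auc(scores, times, events, horizons[i], B = B,
                    conf_level = conf_level, seed = seed + i),
      error = function(e) {
        warning("horizon ", horizons[i], " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(pt)) pts[[length(pts) + 1]] <- pt
  }
  structure(pts, class = "time_auc_curve")
}

#' Calibration table at a horizon
#'
#' Patients are grouped into quantile bins of predicted conception
#' probability; within each bin the observed frequency is `1 - KM(horizon)`
#' with a Greenwood confidence interval. A bin whose follow-up cannot reach
#' the horizon (no events and no subject followed that far) is flagged
#' unavailable.
#'
#' @param predicted probabilities of the event by `horizon`, in `[0, 1]`.
#' @param times,events follow-up data.
#' @param horizon positive horizon (months).
#' @param n_bins number of quantile bins (default 5).
#' @param conf_level confidence level for the observed frequency.
#' @return data frame of class `calibration_table` with one row per bin:
#'   `bin_index`, `mean_predicted`, `observed`, `n`, `observed_ci_low`,
#'   `observed_ci_high`, `available`.
#' @export
calibration_table <- function(predicted, times, events, horizon, n_bins = 5,
                              conf_level = 0.95) {
  if (any(predicted < 0 | predicted > 1))
    hs_error("invalid-probability", "predictions must lie in [0, 1]")
  breaks <- unique(stats::quantile(predicted, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) == 1) breaks <- c(breaks - 1e-12, breaks + 1e-12)
  bin <- cut(predicted, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(sort(unique(bin)), function(b) {
    in_bin <- bin == b
    km <- kaplan_meier(times[in_bin], events[in_bin])
    reaches <- any(times[in_bin] >= horizon) ||
      (length(km$times) > 0 && max(km$times) >= horizon)
    s <- km_at(km, horizon)
    idx <- findInterval(horizon, km$times)
    se <- if (idx >= 1) km$greenwood_se[idx] else 0
    data.frame(bin_index = b,
               mean_predicted = mean(predicted[in_bin]),
               observed = if (reaches) 1 - s else NA_real_,
               n = sum(in_bin),
               observed_ci_low = if (reaches) max(0, 1 - (s + z * se)) else NA_real_,
               observed_ci_high = if (reaches) min(1, 1 - (s - z * se)) else NA_real_,
               available = reaches)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Paired bootstrap comparison of two models' c-indexes
#'
#' Resamples patients (the same indices for both score vectors), computes the
#' c-index difference in each replicate, and reports a two-sided p-value from
#' the normal approximation to the bootstrap distribution of the difference.
#' Identical score vectors give p = 1 by convention.
#'
#' @param scores_a,scores_b two score vectors for the same patients.
#' @inheritParams harrell_cindex
#' @return a list with `difference`, `p_value`, `B`.
#' @export
compare_cindex <- function(scores_a, scores_b, times, events, B = 1000, seed = 1) {
  stat <- function(s, idx) {
    k <- cindex_counts(s[idx], times[idx], events[idx])
    d <- k$conc + k$disc + k$tied
    if (d == 0) NA_real_ else (k$conc + 0.5 * k$tied) / d
  }
  paired_bootstrap_test(scores_a, scores_b, length(times), stat, B, seed)
}

#' Paired bootstrap comparison of two models' time-dependent AUCs
#'
#' @inheritParams compare_cindex
#' @param horizon horizon (months) at which the AUCs are compared.
#' @export
compare_time_auc <- function(scores_a, scores_b, times, events, horizon,
                             B = 1000, seed = 1) {
  stat <- function(s, idx) {
    tryCatch(ipcw_auc_point(s[idx], times[idx], events[idx], horizon)$auc,
             error = function(e) NA_real_)
  }
  paired_bootstrap_test(scores_a, scores_b, length(times), stat, B, seed)
}

paired_bootstrap_test <- function(scores_a, scores_b, n, stat, B, seed) {
  if (length(scores_a) != n || length(scores_b) != n)
    hs_error("length-mismatch", "score vectors must match the cohort size")
  full <- seq_len(n)
  d_obs <- stat(scores_a, full) - stat(scores_b, full)
  diffs <- with_local_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      stat(scores_a, idx) - stat(scores_b, idx)
    }, numeric(1))
  })
  diffs <- diffs[is.finite(diffs)]
  s <- stats::sd(diffs)
  p <- if (!is.finite(s) || s == 0) {
    if (isTRUE(all.equal(d_obs, 0))) 1 else 0
  } else {
    2 * stats::pnorm(-abs(d_obs) / s)
  }
  list(difference = d_obs, p_value = p, B = B)
}
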