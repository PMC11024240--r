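#' Negative log Cox partial likelihood
#'
#' Computes the negative log partial likelihood of a vector of log-hazard
#' scores under the Cox proportional-hazards model, with Breslow handling of
#' tied event times. The score vector may come from a linear predictor
#' (`beta %*% x`) or from the single output node of a DeepSurv network; the
#' value is invariant to adding any constant to all scores.
#'
#' For each subject `i` with an observed event, the contribution is
#' `log(sum_{j in R(T_i)} exp(score_j)) - score_i`, where the risk set
#' `R(T_i)` contains every subject whose follow-up time is at least `T_i`.
#'
#' @param scores numeric vector of log-hazard scores (finite).
#' @param times positive follow-up times, in months.
#' @param events binary event indicators (1 = ongoing pregnancy achieved).
#' @return a single non-negative number, `-log L`.
#' @examples
#' negative_log_partial_likelihood(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1)) # log(6)
#' @export
negative_log_partial_likelihood <- function(scores, times, events) {
  check_surv_args(scores, times, events)
  n <- length(scores)
  ord <- order(times, decreasing = TRUE)
  s <- scores[ord]
  t_sorted <- times[ord]
  m <- max(s)
  cum <- cumsum(exp(s - m))
  # risk-set denominator for subject i: all j with t_j >= t_i; with the
  # descending sort that is the cumulative sum up to the end of i's tie group
  n_ge <- vapply(times[events == 1], function(ti) sum(times >= ti), integer(1))
  log_denom <- log(cum[n_ge]) + m
  sum(log_denom - scores[events == 1])
}

#' DeepSurv training loss
#'
#' The regularized average negative log partial likelihood used to train the
#' survival network: `nlpl / N_events + lambda * ||theta||^2`, where the
#' squared weight norm is supplied by the caller (the network knows its own
#' weights; this function only owns the survival arithmetic).
#'
#' @inheritParams negative_log_partial_likelihood
#' @param weight_sq_norm squared L2 norm of the network weights.
#' @param lambda non-negative regularization strength.
#' @return the scalar loss.
#' @export
deepsurv_loss <- function(scores, times, events, weight_sq_norm = 0, lambda = 0) {
  if (lambda < 0 || weight_sq_norm < 0)
    hs_error("invalid-penalty", "lambda and weight_sq_norm must be non-negative")
  nlpl <- negative_log_partial_likelihood(scores, times, events)
  nlpl / sum(events) + lambda * weight_sq_norm
}

# Loss and gradient w.r.t. the scores, scaled by 1/N_events, for network
# training. Breslow ties. Returns list(loss, grad).
cox_loss_grad <- function(scores, times, events) {
  check_surv_args(scores, times, events)
  n <- length(scores)
  ne <- sum(events)
  ord <- order(times, decreasing = TRUE)
  s <- scores[ord]
  e <- events[ord]
  t_s <- times[ord]
  m <- max(s)
  exps <- exp(s - m)
  cum <- cumsum(exps)
  # denominator shared across a tie group: cumulative sum at group end
  len <- rle(t_s)$lengths
  grp_end <- cumsum(len)
  grp_start <- grp_end - len + 1L
  denom_idx <- rep(grp_end, len)
  denom <- cum[denom_idx]                      # scaled by exp(-m)
  loss <- sum(e * (log(denom) + m - s)) / ne
  # grad_k = exp(s_k) * sum_{events i with t_i <= t_k} 1/D_i  -  e_k;
  # descending sort puts those events at positions >= the start of k's group
  inv_d <- ifelse(e == 1, 1 / denom, 0)
  cum_from <- rev(cumsum(rev(inv_d)))
  cum_grp <- cum_from[rep(grp_start, len)]
  grad_sorted <- (exps * cum_grp - e) / ne
  grad <- numeric(n)
  grad[ord] <- grad_sorted
  list(loss = loss, grad = grad)
}

#' Fit a linear Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the Breslow-ties log partial likelihood for a linear predictor
#' `beta' x`. This is the package's analytic oracle for the DeepSurv head
#' (a linear, unregularized network must reproduce its risk ranking) and the
#' engine behind the ART-benefit hazard-ratio reports. Supports delayed entry
#' (left truncation) so treatment starting mid-follow-up can be modelled with
#' a time-dependent risk-set convention.
#'
#' Newton-Raphson with step-halving when a step decreases the likelihood;
#' convergence is declared when the log-likelihood changes by less than `tol`.
#' Standard errors come from the inverse observed information.
#'
#' @param covariates numeric matrix, one row per subject (a vector is treated
#'   as a single column).
#' @param times positive follow-up times (months).
#' @param events binary event indicators.
#' @param entry optional vector of delayed-entry times (default 0): a subject
#'   is in the risk set at event time `t` iff `entry < t <= time`.
#' @param max_iter,tol Newton controls.
#' @return an object of class `linear_cox` with elements `beta`,
#'   `standard_errors`, `log_likelihood`, `iterations`, `converged`.
#' @export
fit_linear_cox <- function(covariates, times, events, entry = NULL,
                           max_iter = 50, tol = 1e-9) {
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (length(times) != n || length(events) != n)
    hs_error("length-mismatch", "covariates, times, events must agree in length")
  if (sum(events) < 1) hs_error("no-events", "at least one event required")
  if (any(apply(x, 2, function(col) stats::var(col) == 0)))
    hs_error("constant-covariate", "constant covariate column")
  if (is.null(entry)) entry <- rep(0, n)
  if (any(entry >= times)) hs_error("invalid-entry", "entry must precede exit time")

  p <- ncol(x)
  ev_times <- sort(unique(times[events == 1]))
  loglik_parts <- function(beta, want = "l") {
    eta <- drop(x %*% beta)
    ll <- 0
    g <- numeric(p)
    h <- matrix(0, p, p)
    for (t in ev_times) {
      at_risk <- entry < t & times >= t
      ev <- which(times == t & events == 1)
      d <- length(ev)
      w <- exp(eta[at_risk])
      sw <- sum(w)
      ll <- ll + sum(eta[ev]) - d * log(sw)
      if (want == "lgh") {
        xr <- x[at_risk, , drop = FALSE]
        xbar <- colSums(xr * w) / sw
        g <- g + colSums(x[ev, , drop = FALSE]) - d * xbar
        xxw <- crossprod(xr, xr * w) / sw
        h <- h + d * (xxw - tcrossprod(xbar))
      }
    }
    list(ll = ll, grad = g, info = h)
  }

  beta <- numeric(p)
  prev <- loglik_parts(beta, "lgh")
  converged <- FALSE
  iter <- 0
  trace <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(prev$info, prev$grad),
                     error = function(e) hs_error("singular-information",
                                                  "information matrix is singular"))
    halve <- 0
    repeat {
      cand <- beta + step
      cur <- loglik_parts(cand, "lgh")
      if (is.finite(cur$ll) && cur$ll >= prev$ll - 1e-12) break
      step <- step / 2
      halve <- halve + 1
      if (halve > 30) hs_error("no-ascent", "step halving failed to improve likelihood")
    }
    delta <- abs(cur$ll - prev$ll)
    trace <- c(trace, cur$ll)
    beta <- cand
    prev <- cur
    if (max(abs(beta)) > 20)
      hs_error("divergent-beta",
               "coefficients diverging; likely monotone likelihood (complete separation)")
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    hs_error("non-convergence",
             paste0("Newton-Raphson did not converge in ", max_iter,
                    " iterations; log-likelihood trace: ",
                    paste(signif(trace, 10), collapse = ", ")))
  se <- sqrt(diag(solve(prev$info)))
  structure(list(beta = beta, standard_errors = se,
                 log_likelihood = prev$ll, iterations = iter,
                 converged = converged),
            class = "linear_cox")
}

#' @export
print.linear_cox <- function(x, ...) {
  cat("Linear Cox model (Breslow ties)\n")
  tab <- data.frame(beta = x$beta, se = x$standard_errors,
                    hr = exp(x$beta),
                    z = x$beta / x$standard_errors)
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  print(tab, digits = 4)
  cat("log-likelihood:", format(x$log_likelihood), " iterations:", x$iterations, "\n")
  invisible(x)
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' At each distinct event time `t` the increment is
#' `d_t / sum_{j in R(t)} exp(score_j)`. With all scores zero this is the
#' Nelson-Aalen estimator. The returned curve turns log-hazard scores into
#' survival probabilities via [predicted_event_probability()].
#'
#' @inheritParams negative_log_partial_likelihood
#' @return an object of class `baseline_hazard` with `times` (distinct event
#'   times, increasing) and `cumulative_hazard` (non-decreasing), evaluated as
#'   a right-continuous step function that is 0 before the first event time.
#' @export
breslow_cumulative_hazard <- function(scores, times, events) {
  check_surv_args(scores, times, events)
  ev_times <- sort(unique(times[events == 1]))
  inc <- vapply(ev_times, function(t) {
    d <- sum(times == t & events == 1)
    d / sum(exp(scores[times >= t]))
  }, numeric(1))
  structure(list(times = ev_times, cumulative_hazard = cumsum(inc)),
            class = "baseline_hazard")
}

#' Evaluate a cumulative-hazard curve
#'
#' Right-continuous step evaluation; 0 before the first event time.
#'
#' @param curve a `baseline_hazard` object.
#' @param t times at which to evaluate (vectorized).
#' @export
cumulative_hazard_at <- function(curve, t) {
  stopifnot(inherits(curve, "baseline_hazard"))
  idx <- findInterval(t, curve$times)
  c(0, curve$cumulative_hazard)[idx + 1]
}

#' Predicted event probability at a horizon
#'
#' Converts a patient's log-hazard score and the Breslow baseline hazard into
#' the probability of conception by `horizon`:
#' `1 - exp(-H0(horizon) * exp(log_hazard))`. Monotone non-decreasing in both
#' the horizon and the score.
#'
#' @param log_hazard numeric vector of patient log-hazard scores.
#' @param curve a `baseline_hazard` object.
#' @param horizon positive horizon (months).
#' @return probabilities in `[0, 1]`, one per score.
#' @export
predicted_event_probability <- function(log_hazard, curve, horizon) {
  if (any(horizon <= 0)) hs_error("invalid-horizon", "horizon must be positive")
  h0 <- cumulative_hazard_at(curve, horizon)
  1 - exp(-h0 * exp(log_hazard))
}

#' Kaplan-Meier product-limit estimator
#'
#' Right-continuous survival step function starting at 1. Used for IPCW
#' censoring weights (with the roles of event and censoring swapped) and for
#' the observed frequencies in calibration tables. Greenwood standard errors
#' are returned for confidence limits.
#'
#' @param times positive follow-up times.
#' @param events binary indicators (1 = the event whose survival function is
#'   estimated).
#' @return object of class `km_curve` with `times`, `n_risk`, `n_event`,
#'   `surv`, `greenwood_se`.
#' @export
kaplan_meier <- function(times, events) {
  n <- length(times)
  if (n == 0) hs_error("empty-input", "no observations")
  if (!all(events %in% c(0, 1))) hs_error("invalid-event", "events must be 0/1")
  ev_times <- sort(unique(times[events == 1]))
  if (length(ev_times) == 0) {
    return(structure(list(times = numeric(0), n_risk = integer(0),
                          n_event = integer(0), surv = numeric(0),
                          greenwood_se = numeric(0)),
                     class = "km_curve"))
  }
  n_risk <- vapply(ev_times, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- surv * sqrt(cumsum(n_event / (n_risk * pmax(n_risk - n_event, 1e-300))))
  structure(list(times = ev_times, n_risk = n_risk, n_event = n_event,
                 surv = surv, greenwood_se = gw),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#'
#' @param curve a `km_curve`.
#' @param t evaluation times (vectorized).
#' @param left if `TRUE`, return the left limit `S(t-)` (used for censoring
#'   weights at event times).
#' @export
km_at <- function(curve, t, left = FALSE) {
  stopifnot(inherits(curve, "km_curve"))
  if (length(curve$times) == 0) return(rep(1, length(t)))
  idx <- if (left) findInterval(t, curve$times, left.open = TRUE)
         else findInterval(t, curve$times)
  c(1, curve$surv)[idx + 1]
}
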