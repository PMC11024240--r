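#' Assign patients to risk groups by predicted 1-year conception probability
#'
#' Two groups split at the threshold (default 0.5); a probability exactly on
#' the threshold goes to the low-probability group (documented tie rule).
#'
#' @param probabilities_1yr predicted conception probabilities in `[0, 1]`.
#' @param threshold cut-point, default 0.5.
#' @return factor with levels `"low"`, `"high"` ("low" = low conception
#'   probability, i.e. the poor-prognosis group).
#' @export
assign_risk_groups <- function(probabilities_1yr, threshold = 0.5) {
  if (length(probabilities_1yr) == 0) hs_error("empty-input", "no probabilities")
  if (any(probabilities_1yr < 0 | probabilities_1yr > 1))
    hs_error("invalid-probability", "probabilities must lie in [0, 1]")
  factor(ifelse(probabilities_1yr <= threshold, "low", "high"),
         levels = c("low", "high"))
}

#' ART-benefit hazard ratio within one stratum
#'
#' Fits a Cox model with the single binary ART covariate on the patients of
#' one stratum and reports `HR = exp(beta)`, the Wald 95 percent CI, and the
#' two-sided Wald p-value. Under the default baseline-covariate convention
#' ART is a time-fixed covariate from surgery; with
#' `time_dependent = TRUE`, ART patients contribute an untreated interval
#' `[0, art_start)` and a treated interval `[art_start, T]`, avoiding
#' immortal-time bias when ART begins mid-follow-up.
#'
#' @param times,events,art stratum follow-up data and ART indicator.
#' @param time_dependent use the time-dependent ART convention.
#' @param art_start_month ART initiation month (needed when
#'   `time_dependent = TRUE`).
#' @param stratifier,stratum_label labels carried into the report.
#' @param conf_level Wald confidence level.
#' @return object of class `stratum_report` (a one-row data frame):
#'   `stratifier`, `stratum_label`, `hr`, `ci_low`, `ci_high`, `p`, `n`,
#'   `n_events`, `separation`.
#' @export
art_benefit_hr <- function(times, events, art, time_dependent = FALSE,
                           art_start_month = 12, stratifier = "model",
                           stratum_label = "", conf_level = 0.95) {
  if (length(unique(art)) < 2)
    hs_error("no-contrast", "stratum contains a single ART arm")
  if (sum(events) < 1) hs_error("no-events", "stratum has no events")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  fit_or_sep <- function(xm, tt, ee, entry) {
    tryCatch(list(fit = fit_linear_cox(xm, tt, ee, entry = entry), sep = FALSE),
             error = function(e) {
               if (inherits(e, "hysterosurv_error") &&
                   grepl("divergent-beta", conditionMessage(e)))
                 list(fit = NULL, sep = TRUE)
               else stop(e)
             })
  }
  if (!time_dependent) {
    res <- fit_or_sep(matrix(as.numeric(art), ncol = 1), times, events, NULL)
  } else {
    is_art <- art == 1 & times > art_start_month
    t1 <- c(times[!is_art], rep(art_start_month, sum(is_art)), times[is_art])
    e1 <- c(events[!is_art], rep(0, sum(is_art)), events[is_art])
    x1 <- c(as.numeric(art[!is_art]) * 0, rep(0, sum(is_art)), rep(1, sum(is_art)))
    en <- c(rep(0, sum(!is_art)), rep(0, sum(is_art)),
            rep(art_start_month, sum(is_art)))
    res <- fit_or_sep(matrix(x1, ncol = 1), t1, e1, en)
  }
  if (res$sep) {
    out <- data.frame(stratifier = stratifier, stratum_label = stratum_label,
                      hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, n = length(times), n_events = sum(events),
                      separation = TRUE, stringsAsFactors = FALSE)
  } else {
    b <- res$fit$beta[1]; se <- res$fit$standard_errors[1]
    out <- data.frame(stratifier = stratifier, stratum_label = stratum_label,
                      hr = exp(b), ci_low = exp(b - z * se),
                      ci_high = exp(b + z * se),
                      p = 2 * stats::pnorm(-abs(b / se)),
                      n = length(times), n_events = sum(events),
                      separation = FALSE, stringsAsFactors = FALSE)
  }
  class(out) <- c("stratum_report", "data.frame")
  out
}

#' Stratified ART-benefit table
#'
#' One hazard-ratio row per stratum per stratifier: the model's predicted
#' 1-year conception probability (cut at `threshold`), and the clinical
#' comparators AFS (>= 5 vs < 5), CSGE (>= 18 vs < 18) and endometrial
#' thickness (>= 7 mm vs < 7 mm). Strata without both ART arms are reported
#' with `NA` estimates and a note instead of failing the whole table.
#'
#' @param records cohort data frame with columns `time_months`, `event`,
#'   `art`, and (for the clinical stratifiers) `afs`, `csge`, `emt_mm`.
#' @param probabilities_1yr model-predicted 1-year conception probabilities
#'   (needed for the `"model"` stratifier).
#' @param threshold model-probability cut-point.
#' @param stratifiers subset of `c("model", "afs", "csge", "emt")`.
#' @param time_dependent,art_start_month passed to [art_benefit_hr()].
#' @return data frame of class `stratum_table`.
#' @export
stratification_table <- function(records, probabilities_1yr = NULL,
                                 threshold = 0.5,
                                 stratifiers = c("model", "afs", "csge", "emt"),
                                 time_dependent = FALSE, art_start_month = 12) {
  stratifiers <- match.arg(stratifiers, several.ok = TRUE)
  defs <- list()
  if ("model" %in% stratifiers) {
    if (is.null(probabilities_1yr))
      hs_error("missing-predictions", "model stratifier needs probabilities_1yr")
    g <- assign_risk_groups(probabilities_1yr, threshold)
    defs$model <- list(groups = g,
                       labels = c(low = paste0("<", threshold),
                                  high = paste0(">", threshold)))
  }
  if ("afs" %in% stratifiers)
    defs$afs <- list(groups = factor(ifelse(records$afs >= 5, "low", "high"),
                                     levels = c("low", "high")),
                     labels = c(low = "AFS >=5", high = "AFS <5"))
  if ("csge" %in% stratifiers)
    defs$csge <- list(groups = factor(ifelse(records$csge >= 18, "low", "high"),
                                      levels = c("low", "high")),
                      labels = c(low = "CSGE >=18", high = "CSGE <18"))
  if ("emt" %in% stratifiers)
    defs$emt <- list(groups = factor(ifelse(records$emt_mm >= 7, "high", "low"),
                                     levels = c("high", "low")),
                     labels = c(high = "EMT >=7 mm", low = "EMT <7 mm"))
  rows <- list()
  for (nm in names(defs)) {
    d <- defs[[nm]]
    for (lev in levels(d$groups)) {
      in_s <- d$groups == lev
      row <- tryCatch(
        art_benefit_hr(records$time_months[in_s], records$event[in_s],
                       records$art[in_s], time_dependent = time_dependent,
                       art_start_month = art_start_month,
                       stratifier = nm, stratum_label = unname(d$labels[lev])),
        error = function(e) {
          data.frame(stratifier = nm, stratum_label = unname(d$labels[lev]),
                     hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     p = NA_real_, n = sum(in_s),
                     n_events = sum(records$event[in_s]),
                     separation = FALSE, stringsAsFactors = FALSE)
        })
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stratum_table", "data.frame")
  out
}
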