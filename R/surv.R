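# Survival stratification: median-expression dichotomy, Kaplan-Meier
# product-limit curves with an optional follow-up horizon (administrative
# censoring at 3 or 5 years), log-rank comparison and the observed/expected
# hazard-ratio summary.

#' Stratify subjects by median expression
#'
#' Subjects with expression strictly above the median go to the "high"
#' stratum; ties at the median go to "low" (deterministic rule).
#'
#' @param table Survival data.frame with an `expression` column (>= 4 rows).
#' @return Factor of "high"/"low" labels aligned to the rows.
#' @export
stratify_by_median <- function(table) {
  stopifnot(is.data.frame(table), "expression" %in% names(table))
  if (nrow(table) < 4) nm_stop("stratify_by_median needs >= 4 subjects")
  if (length(unique(table$expression)) == 1) {
    nm_stop("all expression values identical: no stratification possible")
  }
  med <- stats::median(table$expression)
  factor(ifelse(table$expression > med, "high", "low"), levels = c("high", "low"))
}

apply_horizon <- function(times, events, horizon) {
  if (is.null(horizon)) return(list(time = times, event = events))
  horizon <- check_positive(horizon, "horizon")
  over <- times > horizon
  list(time = pmin(times, horizon), event = ifelse(over, 0L, events))
}

#' Kaplan-Meier product-limit curve
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i). An optional
#' horizon administratively censors all follow-up beyond it before
#' estimation.
#'
#' @param times Positive follow-up times.
#' @param events Binary event indicators (1 = event, 0 = censored).
#' @param horizon Optional follow-up horizon (e.g. 3 or 5 years).
#' @return data.frame over distinct event times: time, n_risk, n_event,
#'   survival.
#' @export
km_curve <- function(times, events, horizon = NULL) {
  if (!length(times)) nm_stop("km_curve requires at least one subject")
  if (length(times) != length(events)) nm_stop("times/events length mismatch")
  if (any(times <= 0)) nm_stop("times must be > 0")
  if (!all(events %in% c(0, 1))) nm_stop("events must be 0/1")
  h <- apply_horizon(times, events, horizon)
  fit <- survival::survfit(survival::Surv(h$time, h$event) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep],
             n_risk = fit$n.risk[keep],
             n_event = fit$n.event[keep],
             survival = fit$surv[keep],
             row.names = NULL)
}

#' Log-rank comparison of two survival groups
#'
#' Standard log-rank chi-square (1 df) with the hazard ratio summarized
#' from the observed/expected event counts: HR = (O1/E1) / (O2/E2), group 1
#' relative to group 2.
#'
#' @param group1,group2 data.frames with `time` and `event` columns.
#' @param horizon Optional follow-up horizon applied to both groups.
#' @return List: chi2, p, hazard_ratio, observed (length 2), expected
#'   (length 2), horizon.
#' @export
logrank <- function(group1, group2, horizon = NULL) {
  for (g in list(group1, group2)) {
    if (!is.data.frame(g) || !nrow(g) || !all(c("time", "event") %in% names(g))) {
      nm_stop("logrank requires non-empty data.frames with time and event")
    }
  }
  h1 <- apply_horizon(group1$time, group1$event, horizon)
  h2 <- apply_horizon(group2$time, group2$event, horizon)
  time <- c(h1$time, h2$time)
  event <- c(h1$event, h2$event)
  grp <- rep(1:2, c(nrow(group1), nrow(group2)))
  if (sum(event) == 0) nm_stop("logrank undefined: no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  obs <- as.numeric(sd$obs)
  expd <- as.numeric(sd$exp)
  if (any(expd == 0)) nm_stop("logrank undefined: a group has zero expected events")
  chi2 <- as.numeric(sd$chisq)
  list(chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       hazard_ratio = (obs[1] / expd[1]) / (obs[2] / expd[2]),
       observed = obs, expected = expd, horizon = horizon)
}

#' Median-stratified survival analysis of one gene
#'
#' Convenience wrapper: stratify a survival table at the median expression,
#' estimate per-stratum KM curves and run the log-rank comparison
#' (high vs low).
#'
#' @param table Survival data.frame (subject, time, event, expression).
#' @param horizon Optional follow-up horizon.
#' @return List: strata (factor), km (named list of KM data.frames),
#'   comparison (from [logrank()]).
#' @export
survival_by_median <- function(table, horizon = NULL) {
  strata <- stratify_by_median(table)
  hi <- table[strata == "high", , drop = FALSE]
  lo <- table[strata == "low", , drop = FALSE]
  list(strata = strata,
       km = list(high = km_curve(hi$time, hi$event, horizon),
                 low = km_curve(lo$time, lo$event, horizon)),
       comparison = logrank(hi, lo, horizon))
}
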