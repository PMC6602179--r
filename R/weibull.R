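#' Weibull proportional-hazards log-likelihood for right-censored data
#'
#' With baseline hazard \eqn{h_0(t) = \delta t^{\delta-1}} and linear
#' predictor \eqn{\eta} on the log-hazard scale, the contribution of record j
#' is \eqn{e_j(\log\delta + (\delta-1)\log t_j + \eta_j) - t_j^\delta
#' e^{\eta_j}} (log hazard at the event time for deaths, minus the cumulative
#' hazard for everyone).
#'
#' @param time Positive survival/censoring times (months).
#' @param event 0/1 event indicators (1 = death).
#' @param eta Linear predictor, recycled if scalar.
#' @param delta Weibull shape, > 0.
#' @return The log-likelihood (a single number).
#' @export
weibull_ph_loglik <- function(time, event, eta, delta) {
  if (length(event) != length(time)) abort("time and event lengths differ")
  if (length(eta) == 1) eta <- rep(eta, length(time))
  if (length(eta) != length(time)) abort("eta length mismatch")
  if (any(time <= 0)) abort("all times must be > 0")
  if (!all(event %in% c(0, 1))) abort("event must be 0/1")
  if (delta <= 0) abort("delta must be > 0")
  sum(event * (log(delta) + (delta - 1) * log(time) + eta)) -
    sum(time^delta * exp(eta))
}

#' Weibull proportional-hazards survival function
#'
#' \eqn{S(t) = \exp(-t^\delta e^\eta)}.
#'
#' @param t Nonnegative time(s), months.
#' @inheritParams weibull_ph_loglik
#' @return Survival probabilities in (0, 1].
#' @export
weibull_ph_survival <- function(t, eta, delta) {
  if (any(t < 0)) abort("t must be >= 0")
  if (delta <= 0) abort("delta must be > 0")
  exp(-t^delta * exp(eta))
}

#' Kaplan-Meier proxy for under-five mortality (5q0) per 1000
#'
#' Computes `1000 * (1 - S_KM(60))` from the product-limit estimator, with
#' censored children contributing risk time. This is a proxy for the
#' survey-report U5MR, not the DHS synthetic-cohort life-table statistic;
#' report it alongside the raw death fraction, never interchangeably.
#'
#' @param children Tibble with columns `time_months` and `event`.
#' @return Deaths per 1000 before month 60 (single number).
#' @export
km_5q0 <- function(children) {
  if (nrow(children) == 0) abort("empty record set")
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = children)
  s60 <- summary(fit, times = 60, extend = TRUE)$surv
  1000 * (1 - s60)
}

#' Raw death fraction
#'
#' The crude proportion of children whose death was observed, `mean(event)`.
#' Distinct from [km_5q0()]: censored children dilute the numerator here.
#'
#' @inheritParams km_5q0
#' @return Proportion in `[0, 1]`.
#' @export
death_fraction <- function(children) {
  if (nrow(children) == 0) abort("empty record set")
  mean(children$event)
}
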