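#' Default reference categories for the standard covariates
#'
#' Matches the baseline ("HRR = 1.00") categories of the univariable analysis
#' the generator emulates: female, urban, health-facility delivery, birth
#' order 1-5, mother younger than 19, first birth at 19 or younger, 1-5 live
#' births, primary-or-above education, richest tercile.
#'
#' @return Named list covariate -> reference level.
#' @export
default_references <- function() {
  list(sex = "female", residence = "urban", delivery = "facility",
       birth_order = "1-5", mother_age = "under19", age_first_birth = "le19",
       parity = "1-5", education = "primary_plus", wealth = "richest")
}

#' Univariable Weibull proportional-hazards fit
#'
#' Maximum likelihood over (log delta, intercept, level coefficients) by
#' quasi-Newton (BFGS) with analytic gradient; the intercept absorbs the
#' baseline hazard scale. Hazard-rate ratios, Wald 95\% confidence intervals
#' and Wald p-values (coefficient / SE against the standard normal) are
#' reported per non-reference level; a likelihood-ratio p against the
#' covariate-free model is available as an option.
#'
#' @param data Tibble with `time_months`, `event` and the covariate column.
#' @param covariate Name of one covariate column (categorical or numeric).
#' @param reference Optional reference level.
#' @param p_method `"wald"` (default) or `"lr"`.
#' @return Tibble with one row per non-reference level: `covariate`, `level`,
#'   `estimate`, `se`, `hrr`, `ci_lower`, `ci_upper`, `p_value`, `converged`.
#'   The fitted Weibull shape and the maximised log-likelihood are attached as
#'   attributes `delta` and `loglik`.
#' @export
fit_univariable <- function(data, covariate, reference = NULL,
                            p_method = c("wald", "lr")) {
  p_method <- match.arg(p_method)
  x <- data[[covariate]]
  if (is.null(x)) abort(paste0("covariate '", covariate, "' not found"))
  keep <- !is.na(x)
  data <- data[keep, ]
  if (length(unique(data[[covariate]])) < 2) {
    abort(paste0("covariate '", covariate, "' is constant"))
  }
  if (sum(data$event) < 1) abort("need at least one event")
  ref <- list(); ref[[covariate]] <- reference
  X <- build_design(data, covariate, reference = if (is.null(reference)) NULL else ref)
  fit <- weibull_ph_mle(data$time_months, data$event, X)
  j <- setdiff(seq_len(ncol(X)), 1)  # non-intercept columns
  est <- fit$coef[j]; se <- fit$se[j]
  pv <- 2 * pnorm(-abs(est / se))
  if (p_method == "lr") {
    fit0 <- weibull_ph_mle(data$time_months, data$event,
                           X[, 1, drop = FALSE])
    lr_stat <- 2 * (fit$loglik - fit0$loglik)
    pv_lr <- stats::pchisq(lr_stat, df = length(j), lower.tail = FALSE)
    pv <- rep(pv_lr, length(j))
  }
  lvl <- sub(paste0("^", covariate, "_"), "", names(est))
  out <- tibble::tibble(
    covariate = covariate, level = lvl, estimate = unname(est),
    se = unname(se), hrr = exp(unname(est)),
    ci_lower = exp(unname(est - 1.96 * se)),
    ci_upper = exp(unname(est + 1.96 * se)),
    p_value = unname(pv), converged = fit$converged)
  attr(out, "delta") <- fit$delta
  attr(out, "loglik") <- fit$loglik
  out
}

# BFGS maximisation of the right-censored Weibull PH log-likelihood in
# (log delta, beta); analytic gradient; SEs from the numeric Hessian
weibull_ph_mle <- function(time, event, X) {
  logt <- log(time)
  negll <- function(par) {
    delta <- exp(par[1]); b <- par[-1]
    eta <- drop(X %*% b)
    -(sum(event * (par[1] + (delta - 1) * logt + eta)) -
        sum(time^delta * exp(eta)))
  }
  neggrad <- function(par) {
    delta <- exp(par[1]); b <- par[-1]
    eta <- drop(X %*% b)
    cumh <- time^delta * exp(eta)
    d_ldelta <- sum(event * (1 + delta * logt)) - delta * sum(cumh * logt)
    d_b <- drop(crossprod(X, event - cumh))
    -c(d_ldelta, d_b)
  }
  start <- c(0, rep(0, ncol(X)))
  opt <- optim(start, negll, neggrad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12), hessian = TRUE)
  se <- rep(NA_real_, ncol(X))
  ok <- opt$convergence == 0
  cov <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) <= 0)) {
    ok <- FALSE
  } else {
    se <- sqrt(diag(cov))[-1]
  }
  coef <- opt$par[-1]; names(coef) <- colnames(X); names(se) <- colnames(X)
  list(delta = exp(opt$par[1]), coef = coef, se = se, loglik = -opt$value,
       converged = ok)
}

#' Pre-selection screening of candidate covariates
#'
#' Fits one univariable Weibull PH model per covariate and keeps those with
#' p-value strictly below the threshold (default 0.15); for multi-level
#' covariates the minimum level-wise p decides. Covariates whose fit fails or
#' does not converge are flagged and excluded with a warning.
#'
#' @param children Child-record tibble.
#' @param covariates Character vector of candidate covariate columns.
#' @param threshold Inclusion threshold on the p-value (strict `<`).
#' @param reference Optional named list of reference levels; defaults to
#'   [default_references()] where applicable.
#' @param p_method Passed to [fit_univariable()].
#' @return A tibble (class `svc_screening`) with one row per covariate level
#'   plus the logical `included`; the selected covariate names are in
#'   `attr(, "included")`.
#' @export
screen_covariates <- function(children, covariates, threshold = 0.15,
                              reference = NULL, p_method = "wald") {
  refs <- utils::modifyList(default_references(), as.list(reference %||% list()))
  rows <- list(); included <- character()
  for (nm in covariates) {
    res <- tryCatch(
      fit_univariable(children, nm, reference = refs[[nm]],
                      p_method = p_method),
      error = function(e) e)
    if (inherits(res, "error") || !all(res$converged)) {
      warn(paste0("covariate '", nm, "' excluded from screening: ",
                  if (inherits(res, "error")) conditionMessage(res)
                  else "fit did not converge"))
      if (!inherits(res, "error")) {
        res$included <- FALSE
        rows[[nm]] <- res
      }
      next
    }
    res$included <- min(res$p_value) < threshold
    if (res$included[1]) included <- c(included, nm)
    rows[[nm]] <- res
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "included") <- included
  attr(out, "threshold") <- threshold
  class(out) <- c("svc_screening", class(out))
  out
}

#' Covariates selected by a screening table
#' @param screening Result of [screen_covariates()].
#' @return Character vector.
#' @export
included_covariates <- function(screening) attr(screening, "included")
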