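#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted model
#'
#' One row per model parameter with posterior median, equal-tailed 95\%
#' credible interval and PSRF. With `exponentiate = TRUE` the coefficient
#' rows (`beta_*`, `a`, `w_*`) are reported as hazard-rate ratios (the
#' quantiles are exp-transformed, which commutes with the monotone map).
#'
#' @param x An `svc_fit`.
#' @param exponentiate Report coefficients as HRRs.
#' @param ... Unused.
#' @return A tibble with `term`, `median`, `lower`, `upper`, `psrf`.
#' @method tidy svc_fit
#' @export
tidy.svc_fit <- function(x, exponentiate = FALSE, ...) {
  s <- summarize_draws(x)
  if (exponentiate) {
    co <- grepl("^beta_|^w_", s$term) | s$term == "a"
    s$median[co] <- exp(s$median[co])
    s$lower[co] <- exp(s$lower[co])
    s$upper[co] <- exp(s$upper[co])
  }
  s
}

#' One-row fit overview
#'
#' @param x An `svc_fit`.
#' @param ... Unused.
#' @return Tibble with draw counts, the worst PSRF over (delta, beta, a), and
#'   the range of block acceptance rates.
#' @method glance svc_fit
#' @export
glance.svc_fit <- function(x, ...) {
  s <- summarize_draws(x)
  core <- grepl("^beta_", s$term) | s$term %in% c("delta", "a")
  accs <- unlist(x$acceptance)
  tibble::tibble(
    n_chains = length(x$draws),
    n_draws = nrow(x$draws[[1]]) * length(x$draws),
    n_iterations = x$config$n_iterations,
    burn_in = x$config$burn_in,
    max_psrf_core = max(s$psrf[core]),
    min_acceptance = min(accs),
    max_acceptance = max(accs))
}

#' @method tidy protective_counts
#' @export
tidy.protective_counts <- function(x, ...) x$counts

#' @method glance protective_counts
#' @export
glance.protective_counts <- function(x, ...) {
  tibble::tibble(min = x$min, median = x$median, max = x$max)
}
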