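#' Forest plot of hazard-rate ratios
#'
#' National and regional HRRs with 95\% credible intervals on a log scale;
#' the dashed line marks HRR = 1 and importance is colour-coded.
#'
#' @param hrr_table An `hrr_table` from [regional_hrr()] or any tibble with
#'   `scope`/`region`, `hrr`, `lower`, `upper`.
#' @return A ggplot object.
#' @export
plot_hrr_forest <- function(hrr_table) {
  tab <- tibble::as_tibble(hrr_table)
  if (!"scope" %in% names(tab) && "region" %in% names(tab)) {
    tab <- dplyr::rename(tab, scope = "region")
  }
  if (!"important" %in% names(tab)) {
    tab <- dplyr::bind_cols(tab, flag_importance(tab$hrr, tab$lower, tab$upper))
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$hrr,
                                    y = stats::reorder(.data$scope, .data$hrr),
                                    colour = .data$important)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard rate ratio (95% BCI)", y = NULL,
                  colour = "interval excludes 1") +
    ggplot2::theme_minimal()
}

#' @method autoplot hrr_table
#' @export
autoplot.hrr_table <- function(object, ...) plot_hrr_forest(object)

#' Trace plot of selected parameters
#'
#' @param fit An `svc_fit`.
#' @param pars Parameter names (default: delta, a, the variances).
#' @return A ggplot object with one facet per parameter, coloured by chain.
#' @export
plot_trace <- function(fit, pars = c("delta", "a", "sigma2", "sigmaq2")) {
  pars <- intersect(pars, colnames(fit$draws[[1]]))
  df <- purrr::imap_dfr(fit$draws, function(ch, k) {
    tibble::as_tibble(ch[, pars, drop = FALSE]) |>
      dplyr::mutate(iteration = dplyr::row_number(),
                    chain = factor(k)) |>
      tidyr::pivot_longer(dplyr::all_of(pars), names_to = "term")
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "kept draw", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot svc_fit
#' @export
autoplot.svc_fit <- function(object, ...) plot_trace(object, ...)

#' Kaplan-Meier survival curve of a child cohort
#'
#' @param children Tibble with `time_months`, `event`.
#' @return A ggplot step curve of the product-limit estimate to 60 months.
#' @export
plot_km <- function(children) {
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = children)
  df <- tibble::tibble(time = c(0, fit$time), surv = c(1, fit$surv))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(xlim = c(0, 60), ylim = c(NA, 1)) +
    ggplot2::labs(x = "age (months)", y = "S(t), Kaplan-Meier") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
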