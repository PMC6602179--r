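#' National and regional hazard-rate ratios from posterior draws
#'
#' The national HRR summarises the draws of `exp(a)`; region q summarises
#' `exp(a + w_q)` (quantiles commute with the exponential, so these are the
#' exp-transformed coefficient quantiles). Entries are flagged `important`
#' when the 95\% interval excludes 1 and `protective` when additionally the
#' median is below 1.
#'
#' @param fit An `svc_fit`, or a list/matrix of draws containing columns `a`
#'   and `w_<region>`.
#' @param intervention Optional label carried into the output.
#' @return Tibble (class `hrr_table`) with `intervention`, `scope`
#'   (`"National"` or the region name), `hrr`, `lower`, `upper`, `important`,
#'   `protective`, `psrf`.
#' @export
regional_hrr <- function(fit, intervention = NULL) {
  if (inherits(fit, "svc_fit")) {
    intervention <- intervention %||% fit$model$intervention
    chains <- fit$draws
  } else if (is.matrix(fit)) {
    chains <- list(fit)
  } else {
    chains <- fit
  }
  cols <- colnames(chains[[1]])
  if (!"a" %in% cols) abort("draws lack the national coefficient 'a'")
  wcols <- grep("^w_", cols, value = TRUE)
  hrr_chains <- lapply(chains, function(ch) {
    out <- cbind(National = exp(ch[, "a"]),
                 exp(ch[, "a"] + ch[, wcols, drop = FALSE]))
    colnames(out) <- c("National", sub("^w_", "", wcols))
    out
  })
  s <- summarize_draws(if (length(hrr_chains) > 1) hrr_chains else hrr_chains[[1]])
  out <- tibble::tibble(
    intervention = intervention %||% NA_character_,
    scope = s$term, hrr = s$median, lower = s$lower, upper = s$upper,
    psrf = s$psrf)
  fl <- flag_importance(out$hrr, out$lower, out$upper)
  out$important <- fl$important
  out$protective <- fl$protective
  class(out) <- c("hrr_table", class(out))
  out[, c("intervention", "scope", "hrr", "lower", "upper",
          "important", "protective", "psrf")]
}

#' Effective spatial range from decay-rate draws
#'
#' Per draw, the distance at which the exponential correlation falls to 0.05,
#' `-log(0.05)/rho`; summarised as median and equal-tailed 95\% interval in km.
#'
#' @param rho_draws Positive draws of the decay rate (per km), or an
#'   `svc_fit` (its `rho` column is used).
#' @return Tibble with `range_km`, `lower`, `upper`.
#' @export
effective_range <- function(rho_draws) {
  if (inherits(rho_draws, "svc_fit")) {
    rho_draws <- pooled_draws(rho_draws)[, "rho"]
  }
  if (any(rho_draws <= 0)) abort("rho draws must be > 0")
  r <- RANGE_CONST / rho_draws
  qs <- quantile(r, c(0.5, 0.025, 0.975), names = FALSE)
  tibble::tibble(range_km = qs[1], lower = qs[2], upper = qs[3])
}

#' Flag statistical importance of an HRR interval
#'
#' `important` when the 95\% interval excludes 1 (lower > 1 or upper < 1);
#' `protective` when important with median below 1. Vectorised.
#'
#' @param hrr,lower,upper Posterior median and interval endpoints.
#' @return Tibble with logical columns `important`, `protective`.
#' @export
flag_importance <- function(hrr, lower, upper) {
  if (any(lower > hrr + 1e-12) || any(upper < hrr - 1e-12)) {
    abort("malformed interval: need lower <= median <= upper")
  }
  important <- lower > 1 | upper < 1
  tibble::tibble(important = important,
                 protective = important & hrr < 1)
}

#' Count protective interventions per region
#'
#' Given one HRR interval per (intervention, region), counts per region the
#' interventions whose 95\% interval upper bound lies strictly below 1
#' (associated with a mortality reduction). Harmful-important entries
#' (lower > 1) are never counted. National rows are ignored.
#'
#' @param hrr_table Tibble with columns `intervention`, `region` (or `scope`),
#'   `lower`, `upper`.
#' @return List of class `protective_counts`: `counts` (tibble `region`,
#'   `n_protective`), and scalars `min`, `median`, `max`.
#' @export
count_protective <- function(hrr_table) {
  tab <- tibble::as_tibble(hrr_table)
  if (!"region" %in% names(tab) && "scope" %in% names(tab)) {
    tab <- dplyr::rename(tab, region = "scope")
  }
  stopifnot(all(c("intervention", "region", "lower", "upper") %in% names(tab)))
  tab <- dplyr::filter(tab, .data$region != "National")
  if (anyDuplicated(tab[, c("intervention", "region")])) {
    abort("duplicate (intervention, region) entries")
  }
  counts <- tab |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_protective = sum(.data$upper < 1), .groups = "drop")
  structure(list(counts = counts,
                 min = min(counts$n_protective),
                 median = median(counts$n_protective),
                 max = max(counts$n_protective)),
            class = "protective_counts")
}

#' @export
print.protective_counts <- function(x, ...) {
  cat("protective interventions per region: min ", x$min, ", median ",
      x$median, ", max ", x$max, "\n", sep = "")
  print(x$counts, n = Inf)
  invisible(x)
}

#' Read a printed HRR interval table
#'
#' For running the reporting logic directly on published (median, lower,
#' upper) tables rather than on draws.
#'
#' @param path CSV with columns `intervention`, `region`, `hrr`, `lower`,
#'   `upper` (extra columns kept).
#' @return Tibble.
#' @export
read_printed_hrr <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("intervention", "region", "hrr", "lower", "upper")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("printed table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(tab$lower > tab$hrr) || any(tab$upper < tab$hrr)) {
    abort("malformed interval row(s) in printed table")
  }
  tibble::as_tibble(tab)
}

#' Shipped published HRR intervals (Burkina Faso DHS 2010 analysis)
#'
#' Posterior medians and 95\% credible intervals of the 16 intervention
#' models at national and regional level, as published for the Burkina Faso
#' DHS 2010; used to exercise the table-logic reporting tools.
#'
#' @return Tibble with `intervention`, `region`, `hrr`, `lower`, `upper`,
#'   `starred` (1 when flagged important in the published table).
#' @export
burkina_hrr <- function() {
  read_printed_hrr(system.file("extdata", "burkina_hrr_2010.csv",
                               package = "svcsurv", mustWork = TRUE))
}

#' Cohort bookkeeping percentages
#'
#' Retained-cluster, retained-children and death percentages from raw counts,
#' rounded to one decimal except the death fraction which is conventionally
#' reported as a whole percent.
#'
#' @param n_clusters,total_clusters Clusters analysed / surveyed.
#' @param n_children,total_children Children analysed / recorded.
#' @param n_deaths Deaths among analysed children.
#' @return Tibble with `quantity`, `numerator`, `denominator`, `percent`.
#' @export
cohort_summary <- function(n_clusters, total_clusters, n_children,
                           total_children, n_deaths) {
  tibble::tibble(
    quantity = c("clusters_retained", "children_retained", "deaths"),
    numerator = c(n_clusters, n_children, n_deaths),
    denominator = c(total_clusters, total_children, n_children),
    percent = c(round(100 * n_clusters / total_clusters, 1),
                round(100 * n_children / total_children, 1),
                round(100 * n_deaths / n_children)))
}
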