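#' Default covariate marginals for the synthetic survey
#'
#' Category frequencies of the child, maternal and household covariates in the
#' Burkina Faso DHS 2010 analysis sample. The first level of each covariate is
#' the reference category of the corresponding hazard-ratio contrasts.
#'
#' @return Named list; each element a named probability vector.
#' @export
default_covariate_marginals <- function() {
  list(
    sex             = c(female = 0.491, male = 0.509),
    residence       = c(urban = 0.136, rural = 0.864),
    delivery        = c(facility = 0.670, home = 0.330),
    birth_order     = c(`1-5` = 0.753, `over5` = 0.247),
    mother_age      = c(`under19` = 0.046, `20-35` = 0.753, `over35` = 0.201),
    age_first_birth = c(`le19` = 0.660, `over19` = 0.340),
    parity          = c(`1-5` = 0.710, `over5` = 0.290),
    education       = c(`primary_plus` = 0.140, none = 0.860),
    wealth          = c(richest = 0.337, middle = 0.225, poorer = 0.438)
  )
}

#' Default true covariate coefficients (log hazard-rate ratios)
#'
#' Log HRRs matching the univariable estimates of the DHS 2010 sample, used as
#' generative truth. The intercept is the baseline log hazard scale of the
#' calibration preset, tuned by pilot simulation so that the default survey
#' yields roughly a 9\% observed death fraction.
#'
#' @return Named numeric vector including `"(Intercept)"`.
#' @export
default_true_beta <- function() {
  c("(Intercept)"            = -4.3,
    sex_male                 = log(1.12),
    residence_rural          = log(1.71),
    delivery_home            = log(1.57),
    birth_order_over5        = log(1.26),
    `mother_age_20-35`       = log(0.48),
    mother_age_over35        = log(0.51),
    age_first_birth_over19   = log(1.22),
    parity_over5             = log(1.47),
    education_none           = log(1.72),
    wealth_middle            = log(1.41),
    wealth_poorer            = log(1.62))
}

#' Configuration of the synthetic DHS-like survey generator
#'
#' Defaults emulate the Burkina Faso DHS 2010 study conditions: 13 regions on
#' the shipped adjacency graph, 541 clusters, 13,505 children, right censoring
#' at an interview age uniform on (0, 60] months, covariate marginals matching
#' the published sample composition, and region-level intervention coverage
#' from the shipped coverage table. The spatial parameters default to a GP
#' variance of 0.15 with an effective range near 30 km, and a CAR variance of
#' 0.005 per coverage unit with moderate dependence (gamma = 0.5): the
#' regional coefficient multiplies a coverage covariate of the order of 4-10
#' units, so this yields regional log-hazard swings of roughly +/- 0.5,
#' matching the 2-3x spread of regional under-five mortality seen in these
#' surveys. The intercept of [default_true_beta()] is the calibration preset,
#' tuned by pilot simulation to an overall observed death fraction near 9\%.
#'
#' @param n_regions Number of regions (only used when `graph` is `NULL` and a
#'   synthetic grid graph is wanted instead of the Burkina graph).
#' @param n_clusters,n_children Survey size.
#' @param true_delta Weibull shape (< 1 means hazard declining with age).
#' @param true_beta Named coefficient vector, including `"(Intercept)"`.
#' @param true_a National intervention coefficient per `coverage_unit` of
#'   coverage.
#' @param true_sigma2,true_rho GP frailty variance and decay rate (per km).
#' @param true_sigmaq2,true_gamma CAR variance and spatial dependence.
#' @param coverage_by_region Tibble `region_id` + intervention columns
#'   (proportions); defaults to the shipped table.
#' @param intervention Which coverage column enters the hazard.
#' @param coverage_unit Coverage increment Z is expressed in (default 0.10,
#'   i.e. ten percentage points).
#' @param covariate_marginals Named list of category probabilities; first
#'   category is the reference.
#' @param interview_window_months Censoring horizon (ages at interview are
#'   Uniform(0, window), truncated at 60).
#' @param graph A `region_graph`; default the Burkina 13-region graph when
#'   `n_regions == 13`, otherwise a grid graph.
#' @param layout Tibble `region_id`, `lon`, `lat` of region centres for
#'   cluster placement; defaults to a compacted Burkina layout or the grid.
#' @param seed Integer seed; a fixed seed makes [generate_survey()] output
#'   byte-identical.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_regions = 13,
                       n_clusters = 541,
                       n_children = 13505,
                       true_delta = 0.5,
                       true_beta = default_true_beta(),
                       true_a = log(0.9),
                       true_sigma2 = 0.15,
                       true_rho = 0.1,
                       true_sigmaq2 = 0.005,
                       true_gamma = NULL,
                       coverage_by_region = NULL,
                       intervention = "dpt3_immunization",
                       coverage_unit = 0.10,
                       covariate_marginals = default_covariate_marginals(),
                       interview_window_months = 60,
                       graph = NULL,
                       layout = NULL,
                       seed = 1L) {
  if (is.null(graph)) {
    if (n_regions == 13) {
      graph <- burkina_region_graph()
      if (is.null(layout)) layout <- burkina_region_layout()
    } else {
      graph <- grid_region_graph(n_regions)
      if (is.null(layout)) layout <- attr(graph, "layout")
    }
  } else if (is.null(layout)) {
    layout <- attr(graph, "layout")
    if (is.null(layout)) abort("a custom graph needs a `layout` of region centres")
  }
  if (is.null(true_gamma)) {
    true_gamma <- 0.5 * graph$gamma_bounds[2]  # moderate positive dependence
  }
  if (is.null(coverage_by_region)) {
    cov_tab <- burkina_coverage()
    if (!setequal(cov_tab$region_id, graph$region_ids)) {
      # synthetic graph: spread coverage evenly over the published range
      cov_tab <- tibble::tibble(
        region_id = graph$region_ids,
        value = seq(0.4, 0.95, length.out = length(graph$region_ids)))
      names(cov_tab)[2] <- intervention
    }
    coverage_by_region <- cov_tab
  }
  cfg <- list(
    n_regions = length(graph$region_ids), n_clusters = n_clusters,
    n_children = n_children, true_delta = true_delta, true_beta = true_beta,
    true_a = true_a, true_sigma2 = true_sigma2, true_rho = true_rho,
    true_sigmaq2 = true_sigmaq2, true_gamma = true_gamma,
    coverage_by_region = as_coverage(coverage_by_region),
    intervention = intervention, coverage_unit = coverage_unit,
    covariate_marginals = covariate_marginals,
    interview_window_months = interview_window_months,
    graph = graph, layout = layout, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$true_delta <= 0) abort("true_delta must be > 0")
  if (cfg$true_sigma2 <= 0 || cfg$true_sigmaq2 <= 0 || cfg$true_rho <= 0) {
    abort("variances and rho must be > 0")
  }
  gb <- cfg$graph$gamma_bounds
  if (cfg$true_gamma <= gb[1] || cfg$true_gamma >= gb[2]) {
    abort(sprintf("true_gamma must lie strictly inside (%.3f, %.3f)", gb[1], gb[2]))
  }
  for (nm in names(cfg$covariate_marginals)) {
    p <- cfg$covariate_marginals[[nm]]
    if (abs(sum(p) - 1) > 1e-6) {
      abort(paste0("marginal probabilities for '", nm, "' do not sum to 1"))
    }
  }
  if (!cfg$intervention %in% names(cfg$coverage_by_region)) {
    abort(paste0("intervention '", cfg$intervention, "' not in coverage table"))
  }
  if (!setequal(cfg$coverage_by_region$region_id, cfg$graph$region_ids)) {
    abort("coverage table regions do not match the graph")
  }
  if (!setequal(cfg$layout$region_id, cfg$graph$region_ids)) {
    abort("layout regions do not match the graph")
  }
  if (cfg$interview_window_months <= 0) abort("interview window must be > 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_children, " children / ", x$n_clusters,
      " clusters / ", x$n_regions, " regions; intervention = ",
      x$intervention, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Region-centre layout used for synthetic cluster placement
#'
#' Approximate centroids of the 13 regions, compacted towards their mean so
#' the whole layout spans roughly 400 x 400 km; clusters are placed uniformly
#' in a box around each centre, which brackets the inter-cluster distances the
#' spatial range priors are designed for.
#'
#' @return Tibble `region_id`, `lon`, `lat`.
#' @export
burkina_region_layout <- function() {
  raw <- tibble::tribble(
    ~region_id,          ~lon,  ~lat,
    "Boucle du Mouhoun", -3.1,  12.40,
    "Cascades",          -4.8,  10.40,
    "Centre",            -1.5,  12.35,
    "Centre-Est",        -0.4,  11.50,
    "Centre-Nord",       -1.2,  13.30,
    "Centre-Ouest",      -2.3,  11.90,
    "Centre-Sud",        -1.3,  11.60,
    "Est",                0.7,  12.20,
    "Hauts Bassins",     -4.3,  11.30,
    "Nord",              -2.4,  13.30,
    "Plateau Central",   -1.0,  12.60,
    "Sahel",             -0.5,  14.00,
    "Sud-Ouest",         -3.2,  10.60)
  # compact longitudes (0.65x about the mean) so the layout is ~400 km wide
  raw$lon <- mean(raw$lon) + 0.65 * (raw$lon - mean(raw$lon))
  raw
}

#' Synthetic grid region graph
#'
#' Arranges `n_regions` nodes on a rectangular grid with rook adjacency plus
#' one diagonal edge, an alternative topology so tests do not depend on the
#' Burkina graph. Region centres (1 degree spacing) are attached as the
#' `layout` attribute.
#'
#' @param n_regions Number of regions (>= 2).
#' @return A `region_graph` with a `layout` attribute.
#' @export
grid_region_graph <- function(n_regions) {
  if (n_regions < 2) abort("need at least 2 regions")
  nc <- ceiling(sqrt(n_regions))
  ids <- sprintf("R%02d", seq_len(n_regions))
  row <- (seq_len(n_regions) - 1) %/% nc
  col <- (seq_len(n_regions) - 1) %% nc
  edges <- list()
  for (i in seq_len(n_regions)) {
    for (j in seq_len(n_regions)) {
      if (j <= i) next
      manh <- abs(row[i] - row[j]) + abs(col[i] - col[j])
      if (manh == 1) edges[[length(edges) + 1]] <- c(ids[i], ids[j])
    }
  }
  # one diagonal to break the pure lattice
  if (n_regions > nc + 1) edges[[length(edges) + 1]] <- c(ids[1], ids[nc + 2])
  edges <- do.call(rbind, edges)
  g <- region_graph(tibble::tibble(from = edges[, 1], to = edges[, 2]),
                    region_ids = ids)
  attr(g, "layout") <- tibble::tibble(region_id = ids,
                                      lon = col * 1.0, lat = 10 + row * 1.0)
  g
}

#' Draw Gaussian-process cluster frailties
#'
#' One (or `n`) draws from \eqn{N(0, \sigma^2 R)} with
#' \eqn{R_{kl} = \exp(-d_{kl}\rho)} over the inter-cluster distances of a
#' spatial frame.
#'
#' @param frame A `spatial_frame` (or a bare distance matrix in km).
#' @param sigma2 GP variance, > 0.
#' @param rho Decay rate per km, > 0.
#' @param n Number of independent draws.
#' @param seed Optional seed for reproducibility.
#' @return A numeric vector (n = 1) or an n x m matrix of frailties.
#' @export
simulate_frailty <- function(frame, sigma2, rho, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- if (inherits(frame, "spatial_frame")) frame$distances else as.matrix(frame)
  S <- gp_covariance(d, sigma2, rho)
  L <- chol_with_jitter(S, sigma2)
  z <- matrix(rnorm(n * nrow(d)), n, nrow(d))
  out <- z %*% L
  if (n == 1) drop(out) else out
}

#' Draw CAR-distributed regional intervention effects
#'
#' One (or `n`) draws from \eqn{N(0, \sigma_q^2 (I - \gamma C)^{-1} D)}.
#'
#' @param graph A `region_graph`.
#' @param sigmaq2 CAR variance, > 0.
#' @param gamma Spatial dependence, strictly inside `graph$gamma_bounds`.
#' @inheritParams simulate_frailty
#' @return A numeric vector (n = 1) or an n x Q matrix.
#' @export
simulate_regional_effects <- function(graph, sigmaq2, gamma, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- car_covariance(graph, sigmaq2, gamma)
  L <- chol(S)
  z <- matrix(rnorm(n * nrow(S)), n, nrow(S))
  out <- z %*% L
  colnames(out) <- graph$region_ids
  if (n == 1) drop(out) else out
}

#' Draw Weibull survival times by inverse-CDF sampling
#'
#' With \eqn{S(t) = \exp(-t^\delta e^\eta)} and U ~ Uniform(0,1), the draw is
#' \eqn{t = (-\log U \, e^{-\eta})^{1/\delta}}. Times are pre-censoring; the
#' survey generator applies interview censoring afterwards.
#'
#' @param eta Per-child linear predictor.
#' @param delta Weibull shape, > 0.
#' @param seed Optional seed.
#' @return Tibble with `time_months` (> 0) and `event` (all 1).
#' @export
simulate_survival_times <- function(eta, delta, seed = NULL) {
  if (delta <= 0) abort("delta must be > 0")
  if (!is.null(seed)) set.seed(seed)
  u <- runif(length(eta))
  t <- (-log(u) * exp(-eta))^(1 / delta)
  tibble::tibble(time_months = t, event = 1L)
}

# floor on simulated survival times (months): guarantees strictly positive
# times and finite log(t) while leaving the Weibull shape recoverable (a
# coarser floor, e.g. a quarter month, puts several percent of deaths in a
# boundary atom and biases the shape estimate upward by ~0.05 at delta = 0.5)
MIN_TIME <- 1e-3

#' Generate a complete synthetic survey with known ground truth
#'
#' Composes the regional-effect, frailty and survival-time simulators with
#' covariate sampling and interview censoring into a full DHS-like survey.
#' With a fixed seed the output (and any files written) is byte-identical
#' across runs.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `children.csv`,
#'   `clusters.csv`, `coverage.csv`, `adjacency.txt` and `truth.json`.
#' @return An object of class `svc_survey`: list with tibbles `children`,
#'   `clusters`, `coverage`, `adjacency`, the `graph`, and `truth` (all true
#'   parameters and latent draws).
#' @export
generate_survey <- function(config, out_dir = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  graph <- config$graph
  regions <- graph$region_ids
  q <- length(regions)

  # clusters: near-equal allocation across regions, uniform in a box around
  # each region centre
  n_per <- rep(config$n_clusters %/% q, q) +
    c(rep(1, config$n_clusters %% q), rep(0, q - config$n_clusters %% q))
  region_of_cluster <- rep(regions, n_per)
  lay <- config$layout[match(region_of_cluster, config$layout$region_id), ]
  clusters <- tibble::tibble(
    cluster_id = sprintf("c%04d", seq_len(config$n_clusters)),
    lon = lay$lon + runif(config$n_clusters, -0.35, 0.35),
    lat = lay$lat + runif(config$n_clusters, -0.30, 0.30),
    region_id = region_of_cluster)
  frame <- spatial_frame(clusters)

  w <- simulate_regional_effects(graph, config$true_sigmaq2, config$true_gamma)
  phi <- simulate_frailty(frame, config$true_sigma2, config$true_rho)

  # children: cluster membership and categorical covariates
  cl_idx <- sample.int(config$n_clusters, config$n_children, replace = TRUE)
  children <- tibble::tibble(
    child_id = sprintf("k%05d", seq_len(config$n_children)),
    cluster_id = clusters$cluster_id[cl_idx])
  for (nm in names(config$covariate_marginals)) {
    p <- config$covariate_marginals[[nm]]
    children[[nm]] <- sample(names(p), config$n_children, replace = TRUE, prob = p)
  }

  X <- build_design(children, names(config$covariate_marginals),
                    reference = lapply(config$covariate_marginals,
                                       function(p) names(p)[1]))
  beta <- config$true_beta
  missing_b <- setdiff(colnames(X), names(beta))
  if (length(missing_b) > 0) {
    abort(paste0("true_beta lacks coefficient(s): ",
                 paste(missing_b, collapse = ", ")))
  }
  z_by_region <- setNames(
    config$coverage_by_region[[config$intervention]][
      match(regions, config$coverage_by_region$region_id)] / config$coverage_unit,
    regions)
  reg_child <- frame$region_of[children$cluster_id]
  eta <- drop(X %*% beta[colnames(X)]) +
    (config$true_a + w[reg_child]) * z_by_region[reg_child] +
    phi[children$cluster_id]

  t_raw <- pmax(simulate_survival_times(eta, config$true_delta)$time_months,
                MIN_TIME)
  cens <- pmin(runif(config$n_children, 0, config$interview_window_months), 60)
  children$time_months <- pmin(t_raw, cens)
  children$event <- as.integer(t_raw < cens)

  truth <- list(
    delta = config$true_delta, beta = as.list(beta), a = config$true_a,
    sigma2 = config$true_sigma2, rho = config$true_rho,
    sigmaq2 = config$true_sigmaq2, gamma = config$true_gamma,
    intervention = config$intervention, coverage_unit = config$coverage_unit,
    w = as.list(setNames(as.numeric(w), regions)),
    phi = as.list(setNames(as.numeric(phi), clusters$cluster_id)),
    seed = config$seed)

  adjacency <- omega_to_edges(graph$omega)
  out <- structure(
    list(children = children, clusters = clusters,
         coverage = config$coverage_by_region, adjacency = adjacency,
         graph = graph, frame = frame, truth = truth, config = config),
    class = "svc_survey")
  if (!is.null(out_dir)) write_survey(out, out_dir)
  out
}

omega_to_edges <- function(omega) {
  idx <- which(upper.tri(omega) & omega == 1, arr.ind = TRUE)
  tibble::tibble(from = rownames(omega)[idx[, 1]],
                 to = colnames(omega)[idx[, 2]])
}

write_survey <- function(survey, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(survey$children, file.path(out_dir, "children.csv"))
  readr::write_csv(survey$clusters, file.path(out_dir, "clusters.csv"))
  readr::write_csv(survey$coverage, file.path(out_dir, "coverage.csv"))
  writeLines(paste(survey$adjacency$from, survey$adjacency$to, sep = "\t"),
             file.path(out_dir, "adjacency.txt"))
  jsonlite::write_json(survey$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.svc_survey <- function(x, ...) {
  cat("<svc_survey> ", nrow(x$children), " children, ",
      nrow(x$clusters), " clusters, ", length(x$graph$region_ids),
      " regions; observed death fraction ",
      sprintf("%.3f", mean(x$children$event)), "\n", sep = "")
  invisible(x)
}

#' Build a dummy-coded design matrix
#'
#' Intercept plus one column per non-reference level of each categorical
#' covariate (named `covariate_level`); numeric covariates pass through.
#'
#' @param data Tibble of records.
#' @param covariates Character vector of column names.
#' @param reference Optional named list of reference levels (default: first
#'   sorted level).
#' @return Numeric matrix with `"(Intercept)"` first.
#' @export
build_design <- function(data, covariates, reference = NULL) {
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  for (nm in covariates) {
    x <- data[[nm]]
    if (is.null(x)) abort(paste0("covariate '", nm, "' not found"))
    if (is.numeric(x)) {
      cols[[nm]] <- x
    } else {
      x <- as.character(x)
      lev <- sort(unique(x))
      ref <- reference[[nm]] %||% lev[1]
      if (!ref %in% lev) abort(paste0("reference level '", ref,
                                      "' absent for '", nm, "'"))
      for (l in setdiff(lev, ref)) {
        cols[[paste(nm, l, sep = "_")]] <- as.numeric(x == l)
      }
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  m
}
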