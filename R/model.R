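#' Gaussian-process covariance with exponential correlogram
#'
#' \eqn{\Sigma = \sigma^2 \exp(-d\rho)} over a distance matrix, with a small
#' diagonal jitter (1e-8 sigma2) so the Cholesky factor exists numerically.
#'
#' @param distances Square symmetric distance matrix (km).
#' @param sigma2 Variance, > 0.
#' @param rho Decay rate per km, > 0.
#' @return Covariance matrix.
#' @export
gp_covariance <- function(distances, sigma2, rho) {
  distances <- as.matrix(distances)
  if (nrow(distances) != ncol(distances)) abort("distance matrix must be square")
  if (sigma2 <= 0 || rho <= 0) abort("sigma2 and rho must be > 0")
  S <- sigma2 * exp(-distances * rho)
  S + diag(1e-8 * sigma2, nrow(S))
}

chol_with_jitter <- function(S, scale) {
  jit <- 1e-8 * scale
  for (k in 1:7) {
    L <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    if (!is.null(L)) {
      if (k > 2) warn(sprintf("covariance jitter escalated to %.1e", jit))
      return(L)
    }
    jit <- jit * 10
  }
  abort("covariance not positive definite even after jitter escalation")
}

#' Support of the GP decay parameter rho
#'
#' The uniform prior bounds (a, b) are chosen so the effective range (the
#' distance at which the correlation drops to 0.05, `-log(0.05)/rho`) lies
#' between the largest and smallest nonzero observed inter-point distances:
#' `a = -log(0.05)/d_max`, `b = -log(0.05)/d_min`.
#'
#' @param distances Distance matrix (km) of the observed locations.
#' @return Numeric `c(a, b)`, per km.
#' @export
rho_bounds <- function(distances) {
  d <- as.matrix(distances)
  pos <- d[upper.tri(d)]
  pos <- pos[pos > 0]
  if (length(pos) == 0) abort("need at least 2 distinct locations")
  c(RANGE_CONST / max(pos), RANGE_CONST / min(pos))
}

#' Proper CAR covariance of the spatially varying coefficients
#'
#' \eqn{\Sigma = \sigma_q^2 (I - \gamma C)^{-1} D} with C the row-normalised
#' proximity matrix and D = diag(1/g_k). For gamma strictly inside the
#' eigenvalue bounds this is symmetric positive definite (D^{-1}(I - gamma C)
#' equals diag(g) - gamma omega, which is symmetric).
#'
#' @param graph A `region_graph`.
#' @param sigmaq2 Variance, > 0.
#' @param gamma Spatial dependence, strictly inside `graph$gamma_bounds`.
#' @return Q x Q covariance matrix.
#' @export
car_covariance <- function(graph, sigmaq2, gamma) {
  if (sigmaq2 <= 0) abort("sigmaq2 must be > 0")
  gb <- graph$gamma_bounds
  if (gamma <= gb[1] || gamma >= gb[2]) {
    abort(sprintf("gamma must lie strictly inside (%.4f, %.4f)", gb[1], gb[2]))
  }
  q <- length(graph$g)
  S <- sigmaq2 * solve(diag(q) - gamma * graph$C) %*% diag(graph$D, q)
  (S + t(S)) / 2
}

# log density of w ~ N(0, sigmaq2 (I - gamma C)^{-1} D), via the sparse
# precision (diag(g) - gamma omega)/sigmaq2 and the eigenvalues of the
# symmetrised proximity: log|Sigma| = Q log sigmaq2 - sum(log g) -
# sum(log(1 - gamma lambda_i))
car_logdens <- function(w, graph, sigmaq2, gamma) {
  q <- length(w)
  quad <- (sum(graph$g * w^2) - gamma * drop(w %*% graph$omega %*% w)) / sigmaq2
  logdet <- q * log(sigmaq2) - sum(log(graph$g)) -
    sum(log1p(-gamma * graph$eigenvalues))
  -0.5 * (q * log(2 * pi) + logdet + quad)
}

gp_logdens <- function(phi, distances, sigma2, rho) {
  S <- gp_covariance(distances, sigma2, rho)
  L <- chol_with_jitter(S, sigma2)
  v <- backsolve(L, phi, transpose = TRUE)
  -0.5 * (length(phi) * log(2 * pi)) - sum(log(diag(L))) - 0.5 * sum(v^2)
}

dinvgamma_log <- function(x, shape, scale) {
  if (x <= 0) return(-Inf)
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Prior specification
#'
#' Defaults follow common practice for these geostatistical survival models:
#' inverse-gamma(2.01, 1.01) on both spatial variances (mean 1, infinite-ish
#' variance), uniform priors on rho (range-in-distance constraint) and gamma
#' (eigenvalue bounds), exponential(0.01) on the Weibull shape, and vague
#' N(0, 10^3) on all regression coefficients including the national
#' intervention effect.
#'
#' @param sigma2_shape,sigma2_scale Inverse-gamma hyperparameters of the GP
#'   variance.
#' @param sigmaq2_shape,sigmaq2_scale Inverse-gamma hyperparameters of the CAR
#'   variance.
#' @param rho_support Optional `c(a, b)`; when `NULL` it is derived from the
#'   data distances at model-assembly time via [rho_bounds()].
#' @param delta_rate Rate of the exponential prior on the Weibull shape.
#' @param beta_var Variance of the normal prior on beta and a.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(sigma2_shape = 2.01, sigma2_scale = 1.01,
                       sigmaq2_shape = 2.01, sigmaq2_scale = 1.01,
                       rho_support = NULL, delta_rate = 0.01,
                       beta_var = 1000) {
  if (!is.null(rho_support) && rho_support[1] >= rho_support[2]) {
    abort("rho_support must satisfy a < b")
  }
  structure(list(sigma2_shape = sigma2_shape, sigma2_scale = sigma2_scale,
                 sigmaq2_shape = sigmaq2_shape, sigmaq2_scale = sigmaq2_scale,
                 rho_support = rho_support, delta_rate = delta_rate,
                 beta_var = beta_var),
            class = "prior_spec")
}

#' Assemble the geostatistical survival model
#'
#' Joins child records, cluster geography, the region graph and the coverage
#' table into a fitting-ready object: design matrix for the adjustment
#' covariates (intercept included), per-child intervention coverage in
#' `coverage_unit` units, index maps child -> cluster -> region, and the data-
#' driven support for rho. Children with missing adjustment covariates are
#' dropped complete-case with a message stating the count.
#'
#' @param children Child-record tibble (see [read_children()]).
#' @param clusters Cluster tibble or a prebuilt `spatial_frame`.
#' @param graph A `region_graph`.
#' @param coverage Coverage tibble (`region_id` + intervention columns,
#'   proportions; percentages are rescaled).
#' @param intervention Name of the coverage column to model.
#' @param adjust Character vector of adjustment covariate columns (typically
#'   the screening output). May be empty.
#' @param coverage_unit Unit of the coverage covariate Z (default 0.10 = ten
#'   percentage points).
#' @param priors A [prior_spec()].
#' @param reference Optional named list of reference levels for `adjust`.
#' @return An object of class `svc_model`.
#' @export
svc_model <- function(children, clusters, graph, coverage, intervention,
                      adjust = character(), coverage_unit = 0.10,
                      priors = prior_spec(), reference = NULL) {
  frame <- if (inherits(clusters, "spatial_frame")) clusters else spatial_frame(clusters)
  coverage <- as_coverage(coverage)
  if (!intervention %in% names(coverage)) {
    abort(paste0("intervention '", intervention, "' not in coverage table"))
  }
  children <- tibble::as_tibble(children)
  unknown_cl <- setdiff(unique(as.character(children$cluster_id)),
                        names(frame$region_of))
  if (length(unknown_cl) > 0) {
    abort(paste0("children reference unknown cluster(s): ",
                 paste(head(unknown_cl, 5), collapse = ", ")))
  }
  if (length(adjust) > 0) {
    cc <- stats::complete.cases(children[, adjust, drop = FALSE])
    if (any(!cc)) {
      message(sum(!cc), " children dropped for missing adjustment covariates")
      children <- children[cc, ]
    }
  }
  regions <- graph$region_ids
  if (!all(unique(frame$region_of) %in% regions)) {
    abort("spatial frame references regions absent from the graph")
  }
  cl_ids <- rownames(frame$distances)
  cluster_idx <- match(as.character(children$cluster_id), cl_ids)
  region_of_cluster <- match(frame$region_of[cl_ids], regions)
  z_region <- coverage[[intervention]][match(regions, coverage$region_id)]
  if (any(is.na(z_region))) abort("coverage table missing some graph regions")
  z_region <- z_region / coverage_unit
  X <- build_design(children, adjust, reference = reference)
  if (is.null(priors$rho_support)) {
    priors$rho_support <- rho_bounds(frame$distances)
  }
  structure(
    list(children = children, time = children$time_months,
         event = as.integer(children$event), X = X,
         cluster_idx = cluster_idx, region_of_cluster = region_of_cluster,
         z_region = z_region, frame = frame, graph = graph,
         intervention = intervention, coverage_unit = coverage_unit,
         priors = priors),
    class = "svc_model")
}

#' @export
print.svc_model <- function(x, ...) {
  cat("<svc_model> ", length(x$time), " children, ",
      nrow(x$frame$distances), " clusters, ", length(x$graph$region_ids),
      " regions; intervention = ", x$intervention, "; ",
      ncol(x$X) - 1, " adjustment column(s)\n", sep = "")
  invisible(x)
}

#' Initial model state
#'
#' @param model An `svc_model`.
#' @param jitter_sd When > 0 the numeric components are perturbed by
#'   N(0, jitter_sd^2) noise (used for overdispersed second chains).
#' @return A named list with elements `delta`, `beta`, `a`, `w`, `phi`,
#'   `sigma2`, `rho`, `sigmaq2`, `gamma`.
#' @export
initial_state <- function(model, jitter_sd = 0) {
  pr <- model$priors
  st <- list(delta = 1, beta = rep(0, ncol(model$X)), a = 0,
             w = rep(0, length(model$graph$region_ids)),
             phi = rep(0, nrow(model$frame$distances)),
             sigma2 = 0.5, rho = mean(pr$rho_support), sigmaq2 = 0.5,
             gamma = 0)
  names(st$beta) <- colnames(model$X)
  if (jitter_sd > 0) {
    st$delta <- st$delta * exp(rnorm(1, 0, jitter_sd))
    st$beta <- st$beta + rnorm(length(st$beta), 0, jitter_sd)
    st$a <- st$a + rnorm(1, 0, jitter_sd)
    st$w <- st$w + rnorm(length(st$w), 0, jitter_sd)
    st$phi <- st$phi + rnorm(length(st$phi), 0, jitter_sd)
    st$sigma2 <- st$sigma2 * exp(rnorm(1, 0, jitter_sd))
    st$sigmaq2 <- st$sigmaq2 * exp(rnorm(1, 0, jitter_sd))
  }
  st
}

state_eta <- function(state, model) {
  drop(model$X %*% state$beta) +
    ((state$a + state$w[model$region_of_cluster]) *
       model$z_region[model$region_of_cluster])[model$cluster_idx] +
    state$phi[model$cluster_idx]
}

#' Joint log posterior (unnormalised)
#'
#' Sum of the right-censored Weibull log-likelihood, the GP log density of the
#' cluster frailties, the CAR log density of the regional effects, and all
#' prior log densities. States outside the prior support return `-Inf` (a
#' sentinel, never an error, so samplers can propose freely).
#'
#' @param state A state list as from [initial_state()].
#' @param model An `svc_model`.
#' @return A single number, possibly `-Inf`.
#' @export
log_posterior <- function(state, model) {
  pr <- model$priors
  gb <- model$graph$gamma_bounds
  if (state$delta <= 0 || state$sigma2 <= 0 || state$sigmaq2 <= 0 ||
      state$rho <= pr$rho_support[1] || state$rho >= pr$rho_support[2] ||
      state$gamma <= gb[1] || state$gamma >= gb[2]) {
    return(-Inf)
  }
  eta <- state_eta(state, model)
  ll <- weibull_ph_loglik(model$time, model$event, eta, state$delta)
  lp <- ll +
    gp_logdens(state$phi, model$frame$distances, state$sigma2, state$rho) +
    car_logdens(state$w, model$graph, state$sigmaq2, state$gamma) +
    dinvgamma_log(state$sigma2, pr$sigma2_shape, pr$sigma2_scale) +
    dinvgamma_log(state$sigmaq2, pr$sigmaq2_shape, pr$sigmaq2_scale) +
    stats::dunif(state$rho, pr$rho_support[1], pr$rho_support[2], log = TRUE) +
    stats::dunif(state$gamma, gb[1], gb[2], log = TRUE) +
    dexp(state$delta, pr$delta_rate, log = TRUE) +
    sum(dnorm(c(state$beta, state$a), 0, sqrt(pr$beta_var), log = TRUE))
  if (!is.finite(lp)) return(-Inf)
  lp
}
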