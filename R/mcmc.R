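#' MCMC configuration
#'
#' Defaults reproduce the estimation protocol of the motivating analysis: two
#' chains of 300,000 iterations with a 15,000-iteration burn-in and
#' Gelman-Rubin convergence assessment. Thinning and the adaptation window
#' are implementation choices (the sampler is an adaptive random-walk
#' Metropolis-within-Gibbs; step sizes and the joint (beta, a) proposal
#' covariance adapt during the window and are frozen afterwards).
#'
#' @param n_iterations Total iterations per chain.
#' @param burn_in Iterations discarded from the front of each chain.
#' @param n_chains Number of chains (>= 2 for diagnostics).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Base seed; chain k uses `seed + k - 1`.
#' @param adapt Length of the adaptation window (default: the burn-in).
#' @param store_phi Keep the per-cluster frailty draws (memory heavy for
#'   long runs).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 300000, burn_in = 15000, n_chains = 2,
                        thin = 30, seed = 1L, adapt = NULL,
                        store_phi = FALSE) {
  adapt <- adapt %||% burn_in
  if (burn_in >= n_iterations) abort("burn_in must be < n_iterations")
  if (thin < 1) abort("thin must be >= 1")
  if (n_chains < 1) abort("need at least one chain")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 seed = as.integer(seed), adapt = as.integer(adapt),
                 store_phi = isTRUE(store_phi)),
            class = "mcmc_config")
}

#' Sample the posterior by adaptive Metropolis-within-Gibbs
#'
#' Update blocks per sweep: (delta) on the log scale; (log delta, beta)
#' jointly with an adapted multivariate normal proposal capturing the
#' shape/baseline-scale ridge; (w | rest) and (phi | rest) as componentwise
#' random-walk scans using the sparse CAR precision and the GP precision; an
#' exact Gibbs recentering of the national effect a against the regional
#' slopes (likelihood-invariant) and of the intercept against the frailty
#' mean; a "level" move trading a common slope shift against the intercept;
#' and (sigma2, rho) and (sigmaq2, gamma) jointly on log / bounded-logit
#' scales. Identical seeds give identical draws.
#'
#' @param model An [svc_model()].
#' @param config An [mcmc_config()].
#' @param init Optional named list overriding components of the default
#'   initial state (chain 2+ still jitters around it).
#' @param fix Character vector of update blocks to skip, holding their
#'   components at the initial values: any of `"delta"`, `"beta"` (which
#'   includes `a`), `"w"`, `"phi"`, `"sigma_rho"`, `"sigmaq_gamma"`. Useful
#'   for sampler validation on low-dimensional reductions.
#' @param prior_only Drop the data likelihood and sample from the joint
#'   prior (a standard sampler-correctness check: the marginal draws of each
#'   hyperparameter must then match its prior).
#' @return An object of class `svc_fit` with per-chain thinned post-burn-in
#'   draw matrices, acceptance rates per block, the model and the config.
#' @export
svc_sample <- function(model, config = mcmc_config(), init = NULL,
                       fix = character(), prior_only = FALSE) {
  chains <- vector("list", config$n_chains)
  accepts <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    set.seed(config$seed + k - 1)
    st <- initial_state(model, jitter_sd = if (k == 1) 0 else 0.1)
    if (!is.null(init)) for (nm in names(init)) st[[nm]] <- init[[nm]]
    if (!is.finite(log_posterior(st, model)) && !prior_only) {
      st <- initial_state(model, jitter_sd = 0.01)
      if (!is.null(init)) for (nm in names(init)) st[[nm]] <- init[[nm]]
      if (!is.finite(log_posterior(st, model))) {
        abort("initial state has -Inf log posterior even after re-initialization")
      }
    }
    run <- run_chain(model, config, st, fix = fix, prior_only = prior_only)
    chains[[k]] <- run$draws
    accepts[[k]] <- run$acceptance
  }
  structure(list(draws = chains, acceptance = accepts, model = model,
                 config = config),
            class = "svc_fit")
}

# one chain of the sampler; heavy lifting with cached linear-predictor pieces
run_chain <- function(model, config, state, fix = character(),
                      prior_only = FALSE) {
  upd <- function(nm) !nm %in% fix
  # data-term wrapper: returns 0 when the likelihood is dropped (prior-only
  # runs), short-circuiting so overflowing likelihood pieces are never formed
  dterm <- function(x) if (prior_only) 0 else x
  time <- model$time; event <- as.numeric(model$event)
  n <- length(time); p <- ncol(model$X)
  Q <- length(model$graph$region_ids); m <- nrow(model$frame$distances)
  logt <- log(time); n_ev <- sum(event); sum_ev_logt <- sum(event * logt)
  region_of_child <- model$region_of_cluster[model$cluster_idx]
  z_child <- model$z_region[region_of_child]
  zbar <- mean(z_child)
  idx_by_cluster <- split(seq_len(n), factor(model$cluster_idx, levels = seq_len(m)))
  idx_by_region <- split(seq_len(n), factor(region_of_child, levels = seq_len(Q)))
  ev_by_cluster <- vapply(idx_by_cluster, function(i) sum(event[i]), 0)
  ev_by_region <- vapply(idx_by_region, function(i) sum(event[i]), 0)
  pr <- model$priors
  gb <- model$graph$gamma_bounds; rb <- pr$rho_support
  g <- model$graph$g; omega <- model$graph$omega; evs <- model$graph$eigenvalues
  distm <- model$frame$distances

  # caches
  Xb <- drop(model$X %*% state$beta)
  eta <- Xb + (state$a + state$w[region_of_child]) * z_child +
    state$phi[model$cluster_idx]
  Eeta <- exp(eta)
  tdelta <- time^state$delta
  S_ev_eta <- sum(event * eta)
  gp <- gp_cache(distm, state$sigma2, state$rho)
  Pphi <- drop(gp$P %*% state$phi)
  car_P <- (diag(g, Q) - state$gamma * omega) / state$sigmaq2
  Pw <- drop(car_P %*% state$w)

  # adaptive step sizes (log scale)
  ls_delta <- log(0.05); ls_sr <- log(0.3); ls_sg <- log(0.3)
  ls_w <- rep(log(0.3), Q); ls_phi <- rep(log(0.3), m)
  ls_beta <- log(0.1); ls_lv <- log(0.1)
  beta_mean <- state$beta[-1]
  beta_M2 <- diag(1e-4, max(p - 1, 1))
  beta_nacc <- 0L; beta_L <- diag(0.05, max(p - 1, 1))
  zc_child <- z_child - zbar
  S_ev_zc <- sum(event * zc_child)
  acc <- c(delta = 0, beta = 0, w = 0, recenter = 0, level = 0, phi = 0,
           sigma_rho = 0, sigmaq_gamma = 0)
  att <- acc

  keep_iters <- seq(config$burn_in + config$thin, config$n_iterations,
                    by = config$thin)
  par_names <- c("delta", paste0("beta_", colnames(model$X)), "a",
                 paste0("w_", model$graph$region_ids),
                 "sigma2", "rho", "sigmaq2", "gamma",
                 if (config$store_phi) paste0("phi_", rownames(distm)))
  draws <- matrix(NA_real_, length(keep_iters), length(par_names),
                  dimnames = list(NULL, par_names))
  keep_ptr <- 1L

  # typical death log-time: the ridge direction for the delta update
  c0 <- if (n_ev > 0) sum_ev_logt / n_ev else 0
  loglik_delta_part <- function(delta, tdel, db0) {
    dterm(n_ev * (log(delta) + db0) + (delta - 1) * sum_ev_logt -
            exp(db0) * sum(tdel * Eeta))
  }

  for (iter in seq_len(config$n_iterations)) {
    adapting <- iter <= config$adapt
    gain <- min(0.05, 1 / sqrt(iter))

    ## -- delta | rest (log-scale RW along the shape/intercept ridge) --------
    # a shape change delta -> delta' rescales the cumulative hazard at the
    # typical death time t* = exp(c0); shifting the intercept by
    # -(delta' - delta) c0 keeps the hazard there fixed, so the walk travels
    # along the weakly identified direction (linear reparametrisation,
    # Jacobian of the log-scale proposal only)
    if (upd("delta")) {
    att["delta"] <- att["delta"] + 1
    ld_prop <- log(state$delta) + exp(ls_delta) * rnorm(1)
    d_prop <- exp(ld_prop)
    td_prop <- if (prior_only) tdelta else time^d_prop
    db0 <- if (upd("beta")) -(d_prop - state$delta) * c0 else 0
    lr <- (loglik_delta_part(d_prop, td_prop, db0) +
             dexp(d_prop, pr$delta_rate, log = TRUE) + ld_prop +
             dnorm(state$beta[1] + db0, 0, sqrt(pr$beta_var), log = TRUE)) -
      (loglik_delta_part(state$delta, tdelta, 0) +
         dexp(state$delta, pr$delta_rate, log = TRUE) + log(state$delta) +
         dnorm(state$beta[1], 0, sqrt(pr$beta_var), log = TRUE))
    a_prob <- min(1, exp(lr))
    if (is.na(a_prob)) a_prob <- 0
    if (runif(1) < a_prob) {
      state$delta <- d_prop; tdelta <- td_prop
      if (db0 != 0) {
        state$beta[1] <- state$beta[1] + db0
        Xb <- Xb + db0
        eta <- eta + db0
        Eeta <- Eeta * exp(db0)
        S_ev_eta <- S_ev_eta + db0 * n_ev
      }
      acc["delta"] <- acc["delta"] + 1
    }
    if (adapting) ls_delta <- ls_delta + gain * (a_prob - 0.44)
    }

    ## -- non-intercept covariate coefficients, jointly -----------------------
    # adapted multivariate normal proposal over the well-identified
    # coefficients only: the intercept and the national effect are excluded
    # because their heavy-tailed ridge marginals would swamp the adapted
    # covariance and freeze this block (they mix through the exact Gibbs
    # recentering and ridge moves instead)
    if (upd("beta") && p > 1) {
    att["beta"] <- att["beta"] + 1
    th <- state$beta[-1]
    th_prop <- th + exp(ls_beta) * drop(beta_L %*% rnorm(p - 1))
    beta_prop <- c(state$beta[1], th_prop)
    Xb_prop <- drop(model$X %*% beta_prop)
    eta_prop <- eta - Xb + Xb_prop
    Eeta_prop <- exp(eta_prop)
    lr <- (dterm(sum(event * eta_prop) - sum(tdelta * Eeta_prop)) +
             sum(dnorm(th_prop, 0, sqrt(pr$beta_var), log = TRUE))) -
      (dterm(S_ev_eta - sum(tdelta * Eeta)) +
         sum(dnorm(th, 0, sqrt(pr$beta_var), log = TRUE)))
    a_prob <- min(1, exp(lr))
    if (is.na(a_prob)) a_prob <- 0
    if (runif(1) < a_prob) {
      state$beta <- beta_prop
      Xb <- Xb_prop; eta <- eta_prop; Eeta <- Eeta_prop
      S_ev_eta <- sum(event * eta)
      acc["beta"] <- acc["beta"] + 1
    }
    if (adapting) {
      ls_beta <- ls_beta + gain * (a_prob - if (p > 2) 0.234 else 0.44)
      # running empirical covariance of the coefficient chain
      beta_nacc <- beta_nacc + 1L
      dlt <- state$beta[-1] - beta_mean
      beta_mean <- beta_mean + dlt / beta_nacc
      beta_M2 <- beta_M2 + outer(dlt, state$beta[-1] - beta_mean)
      if (beta_nacc > 50 && beta_nacc %% 25 == 0) {
        Sg <- beta_M2 / (beta_nacc - 1) + diag(1e-8, p - 1)
        beta_L <- t(chol(2.38^2 / (p - 1) * Sg))
      }
    }
    }

    ## -- w | rest (componentwise scan) --------------------------------------
    if (upd("w")) {
    for (qq in seq_len(Q)) {
      att["w"] <- att["w"] + 1
      dw <- exp(ls_w[qq]) * rnorm(1)
      idx <- idx_by_region[[qq]]
      dz <- dw * model$z_region[qq]
      H_q <- if (length(idx)) sum(tdelta[idx] * Eeta[idx]) else 0
      dll <- dterm(dz * ev_by_region[qq] - (exp(dz) - 1) * H_q)
      dprior <- -0.5 * (car_P[qq, qq] * dw^2 + 2 * dw * Pw[qq])
      a_prob <- min(1, exp(dll + dprior))
      if (runif(1) < a_prob) {
        state$w[qq] <- state$w[qq] + dw
        if (length(idx)) {
          eta[idx] <- eta[idx] + dz
          Eeta[idx] <- Eeta[idx] * exp(dz)
        }
        S_ev_eta <- S_ev_eta + dz * ev_by_region[qq]
        Pw <- Pw + car_P[, qq] * dw
        acc["w"] <- acc["w"] + 1
      }
      if (adapting) ls_w[qq] <- ls_w[qq] + gain * (a_prob - 0.44)
    }
    }

    ## -- recentering Gibbs moves (likelihood-invariant ridges) ---------------
    # (a, w): a <- a + c, w <- w - c leaves every region slope a + w_q (the
    # quantity the likelihood sees) unchanged, so the conditional of c is
    # Gaussian under the CAR prior on w and the vague normal prior on a, and
    # drawing it exactly is a Gibbs update of the national effect given the
    # slopes. Same construction for (beta0, phi) under the GP prior.
    if (upd("beta") && upd("w")) {
    att["recenter"] <- att["recenter"] + 1
    prec_c <- sum(car_P) + 1 / pr$beta_var
    mu_c <- (sum(Pw) - state$a / pr$beta_var) / prec_c
    cshift <- rnorm(1, mu_c, sqrt(1 / prec_c))
    state$a <- state$a + cshift
    state$w <- state$w - cshift
    Pw <- Pw - cshift * rowSums(car_P)
    acc["recenter"] <- acc["recenter"] + 1
    }

    ## -- level move: common slope shift vs intercept -------------------------
    # w <- w + c, beta0 <- beta0 - c zbar moves along the near-ridge between
    # the regional slope level and the intercept; the residual data term only
    # involves c (z - zbar), which is small, so the move travels far
    if (upd("beta") && upd("w")) {
    att["level"] <- att["level"] + 1
    cl_ <- exp(ls_lv) * rnorm(1)
    deta <- cl_ * zc_child
    dll <- dterm(cl_ * S_ev_zc - sum(tdelta * Eeta * expm1(deta)))
    b0_prop <- state$beta[1] - cl_ * zbar
    dprior <- -0.5 * (sum(car_P) * cl_^2 + 2 * cl_ * sum(Pw)) +
      dnorm(b0_prop, 0, sqrt(pr$beta_var), log = TRUE) -
      dnorm(state$beta[1], 0, sqrt(pr$beta_var), log = TRUE)
    a_prob <- min(1, exp(dll + dprior))
    if (is.na(a_prob)) a_prob <- 0
    if (runif(1) < a_prob) {
      state$w <- state$w + cl_
      state$beta[1] <- b0_prop
      Pw <- Pw + cl_ * rowSums(car_P)
      eta <- eta + deta
      Eeta <- Eeta * exp(deta)
      S_ev_eta <- S_ev_eta + cl_ * S_ev_zc
      Xb <- Xb - cl_ * zbar
      acc["level"] <- acc["level"] + 1
    }
    if (adapting) ls_lv <- ls_lv + gain * (a_prob - 0.44)
    }

    if (upd("beta") && upd("phi")) {
    prec_c <- sum(gp$P) + 1 / pr$beta_var
    mu_c <- (sum(Pphi) - state$beta[1] / pr$beta_var) / prec_c
    cshift <- rnorm(1, mu_c, sqrt(1 / prec_c))
    state$beta[1] <- state$beta[1] + cshift
    state$phi <- state$phi - cshift
    Pphi <- Pphi - cshift * rowSums(gp$P)
    Xb <- drop(model$X %*% state$beta)
    }

    ## -- phi | rest (componentwise scan) ------------------------------------
    if (upd("phi")) {
    for (cc in seq_len(m)) {
      att["phi"] <- att["phi"] + 1
      dphi <- exp(ls_phi[cc]) * rnorm(1)
      idx <- idx_by_cluster[[cc]]
      H_c <- if (length(idx)) sum(tdelta[idx] * Eeta[idx]) else 0
      dll <- dterm(dphi * ev_by_cluster[cc] - (exp(dphi) - 1) * H_c)
      dprior <- -0.5 * (gp$P[cc, cc] * dphi^2 + 2 * dphi * Pphi[cc])
      a_prob <- min(1, exp(dll + dprior))
      if (runif(1) < a_prob) {
        state$phi[cc] <- state$phi[cc] + dphi
        if (length(idx)) {
          eta[idx] <- eta[idx] + dphi
          Eeta[idx] <- Eeta[idx] * exp(dphi)
        }
        S_ev_eta <- S_ev_eta + dphi * ev_by_cluster[cc]
        Pphi <- Pphi + gp$P[, cc] * dphi
        acc["phi"] <- acc["phi"] + 1
      }
      if (adapting) ls_phi[cc] <- ls_phi[cc] + gain * (a_prob - 0.44)
    }
    }

    ## -- (sigma2, rho) jointly ----------------------------------------------
    if (upd("sigma_rho")) {
    att["sigma_rho"] <- att["sigma_rho"] + 1
    u <- c(log(state$sigma2), logit_ab(state$rho, rb))
    u_prop <- u + exp(ls_sr) * rnorm(2)
    s2_prop <- exp(u_prop[1]); rho_prop <- inv_logit_ab(u_prop[2], rb)
    gp_prop <- gp_cache(distm, s2_prop, rho_prop)
    cur_gpld <- gp_quad_logdens(state$phi, gp, m)
    prop_gpld <- gp_quad_logdens(state$phi, gp_prop, m)
    lr <- (prop_gpld + dinvgamma_log(s2_prop, pr$sigma2_shape, pr$sigma2_scale) +
             u_prop[1] + log_jac_ab(rho_prop, rb)) -
      (cur_gpld + dinvgamma_log(state$sigma2, pr$sigma2_shape, pr$sigma2_scale) +
         u[1] + log_jac_ab(state$rho, rb))
    a_prob <- min(1, exp(lr))
    if (runif(1) < a_prob) {
      state$sigma2 <- s2_prop; state$rho <- rho_prop
      gp <- gp_prop; Pphi <- drop(gp$P %*% state$phi)
      acc["sigma_rho"] <- acc["sigma_rho"] + 1
    }
    if (adapting) ls_sr <- ls_sr + gain * (a_prob - 0.234)
    }

    ## -- (sigmaq2, gamma) jointly -------------------------------------------
    if (upd("sigmaq_gamma")) {
    att["sigmaq_gamma"] <- att["sigmaq_gamma"] + 1
    u <- c(log(state$sigmaq2), logit_ab(state$gamma, gb))
    u_prop <- u + exp(ls_sg) * rnorm(2)
    sq_prop <- exp(u_prop[1]); gam_prop <- inv_logit_ab(u_prop[2], gb)
    cur_car <- car_quad_logdens(state$w, g, omega, evs, state$sigmaq2, state$gamma)
    prop_car <- car_quad_logdens(state$w, g, omega, evs, sq_prop, gam_prop)
    lr <- (prop_car + dinvgamma_log(sq_prop, pr$sigmaq2_shape, pr$sigmaq2_scale) +
             u_prop[1] + log_jac_ab(gam_prop, gb)) -
      (cur_car + dinvgamma_log(state$sigmaq2, pr$sigmaq2_shape, pr$sigmaq2_scale) +
         u[1] + log_jac_ab(state$gamma, gb))
    a_prob <- min(1, exp(lr))
    if (runif(1) < a_prob) {
      state$sigmaq2 <- sq_prop; state$gamma <- gam_prop
      car_P <- (diag(g, Q) - state$gamma * omega) / state$sigmaq2
      Pw <- drop(car_P %*% state$w)
      acc["sigmaq_gamma"] <- acc["sigmaq_gamma"] + 1
    }
    if (adapting) ls_sg <- ls_sg + gain * (a_prob - 0.234)
    }

    # guard against numerical drift in the incremental caches
    if (iter %% 2000 == 0) {
      eta <- Xb + (state$a + state$w[region_of_child]) * z_child +
        state$phi[model$cluster_idx]
      Eeta <- exp(eta)
      S_ev_eta <- sum(event * eta)
    }

    if (keep_ptr <= length(keep_iters) && iter == keep_iters[keep_ptr]) {
      draws[keep_ptr, ] <- c(state$delta, state$beta, state$a, state$w,
                             state$sigma2, state$rho, state$sigmaq2,
                             state$gamma,
                             if (config$store_phi) state$phi)
      keep_ptr <- keep_ptr + 1L
    }
  }
  list(draws = draws, acceptance = acc / att)
}

gp_cache <- function(distm, sigma2, rho) {
  S <- gp_covariance(distm, sigma2, rho)
  L <- chol_with_jitter(S, sigma2)
  list(P = chol2inv(L), logdet = 2 * sum(log(diag(L))))
}

gp_quad_logdens <- function(phi, gp, m) {
  -0.5 * (m * log(2 * pi) + gp$logdet + drop(phi %*% gp$P %*% phi))
}

car_quad_logdens <- function(w, g, omega, evs, sigmaq2, gamma) {
  q <- length(w)
  quad <- (sum(g * w^2) - gamma * drop(w %*% omega %*% w)) / sigmaq2
  logdet <- q * log(sigmaq2) - sum(log(g)) - sum(log1p(-gamma * evs))
  -0.5 * (q * log(2 * pi) + logdet + quad)
}

logit_ab <- function(x, b) log((x - b[1]) / (b[2] - x))
inv_logit_ab <- function(u, b) b[1] + (b[2] - b[1]) / (1 + exp(-u))
log_jac_ab <- function(x, b) log(x - b[1]) + log(b[2] - x) - log(b[2] - b[1])

#' Gelman-Rubin potential scale reduction factor
#'
#' The common simplified form: with m chains of n draws, within-chain
#' variance W (mean of chain variances) and between-chain variance
#' B = n var(chain means), \eqn{\hat V = (n-1)/n\, W + (1 + 1/m) B / n} and
#' PSRF = sqrt(Vhat / W). The degrees-of-freedom correction of the original
#' 1992 statistic is omitted.
#'
#' @param chains List of numeric matrices (draws x parameters) or vectors,
#'   one per chain, all the same shape.
#' @return Named numeric vector of PSRF values per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2) abort("need at least 2 chains")
  chains <- lapply(chains, function(x) if (is.matrix(x)) x else cbind(par = x))
  n <- nrow(chains[[1]]); m <- length(chains)
  if (n < 10) abort("need at least 10 draws per chain")
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    xs <- vapply(chains, function(ch) ch[, j], numeric(n))
    W <- mean(apply(xs, 2, var))
    B <- n * var(colMeans(xs))
    if (W == 0) return(if (B == 0) 1 else Inf)
    vhat <- (n - 1) / n * W + (1 + 1 / m) * B / n
    sqrt(vhat / W)
  }, 0, USE.NAMES = FALSE) |>
    setNames(colnames(chains[[1]]))
}

#' Pool post-burn-in draws of a fit into one matrix
#' @param fit An `svc_fit`.
#' @return Matrix of pooled draws.
#' @export
pooled_draws <- function(fit) do.call(rbind, fit$draws)

#' Summarise posterior draws
#'
#' Equal-tailed 95\% intervals and medians from the pooled chains (linear-
#' interpolation quantiles), plus the PSRF per parameter when at least two
#' chains are available.
#'
#' @param draws Matrix of draws (columns = parameters), a list of per-chain
#'   matrices, or an `svc_fit`.
#' @return Tibble with `term`, `median`, `lower`, `upper`, `psrf`.
#' @export
summarize_draws <- function(draws) {
  chains <- NULL
  if (inherits(draws, "svc_fit")) {
    chains <- draws$draws
    draws <- pooled_draws(draws)
  } else if (is.list(draws) && !is.data.frame(draws)) {
    chains <- draws
    draws <- do.call(rbind, draws)
  }
  if (!is.matrix(draws)) draws <- cbind(par = draws)
  if (nrow(draws) == 0) abort("no draws to summarise")
  qs <- apply(draws, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  psrf <- if (!is.null(chains) && length(chains) >= 2) {
    gelman_rubin(chains)
  } else {
    rep(NA_real_, ncol(draws))
  }
  tibble::tibble(term = colnames(draws), median = unname(qs[1, ]),
                 lower = unname(qs[2, ]), upper = unname(qs[3, ]),
                 psrf = unname(psrf))
}

#' @export
print.svc_fit <- function(x, ...) {
  cat("<svc_fit> ", length(x$draws), " chain(s) x ", nrow(x$draws[[1]]),
      " kept draws (", x$config$n_iterations, " iterations, burn-in ",
      x$config$burn_in, ", thin ", x$config$thin, ")\n", sep = "")
  cat("intervention: ", x$model$intervention, "\n", sep = "")
  invisible(x)
}
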