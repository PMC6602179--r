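test_that("GP covariance evaluates the exponential correlogram entrywise", {
  set.seed(71)
  pts <- cbind(runif(5, -2, 0), runif(5, 11, 13))
  d <- haversine_matrix(pts)
  S <- gp_covariance(d, sigma2 = 0.4, rho = 0.05)
  expect_equal(unname(diag(S)), rep(0.4 * (1 + 1e-8), 5))
  for (i in 1:5) for (j in 1:5) {
    if (i != j) expect_equal(S[i, j], 0.4 * exp(-d[i, j] * 0.05))
  }
  # at one effective range the correlation is exactly 0.05
  r_eff <- svcsurv:::RANGE_CONST / 0.05
  S2 <- gp_covariance(matrix(c(0, r_eff, r_eff, 0), 2), 1, 0.05)
  expect_equal(S2[1, 2], 0.05, tolerance = 1e-12)
  expect_error(gp_covariance(matrix(1, 2, 3), 1, 1), "square")
})

test_that("rho support spans effective ranges from d_min to d_max", {
  d <- matrix(c(0, 10, 100, 10, 0, 95, 100, 95, 0), 3)
  b <- rho_bounds(d)
  expect_equal(b, -log(0.05) / c(100, 10))
  # inverse relation: range at the bounds reproduces the extreme distances
  expect_equal(-log(0.05) / b[1], 100)
  expect_equal(-log(0.05) / b[2], 10)
  # zeros (duplicate points) are skipped
  ddup <- matrix(c(0, 0, 50, 0, 0, 50, 50, 50, 0), 3)
  expect_equal(rho_bounds(ddup), -log(0.05) / c(50, 50))
  expect_error(rho_bounds(matrix(0, 2, 2)), "distinct")
})

test_that("CAR covariance matches hand-computed cases and stays SPD", {
  g2 <- two_region_graph()
  expect_equal(unname(car_covariance(g2, 3, 0)), 3 * diag(2))
  expect_equal(unname(car_covariance(g2, 1, 0.5)),
               matrix(c(4, 2, 2, 4) / 3, 2))
  expect_error(car_covariance(g2, 1, 1), "gamma")
  expect_error(car_covariance(g2, -1, 0), "sigmaq2")
})

test_that("simulator covariances agree with the model covariances", {
  # the generative and inferential sides use the same matrices: empirical
  # covariance of many draws matches gp_covariance / car_covariance
  # fixtures keep all correlations moderate so the Monte-Carlo error of each
  # empirical entry (sd ~ sqrt(S_ii S_jj + S_ij^2 / n)) sits well inside the
  # 5% band
  set.seed(72)
  pts <- cbind(runif(4, -0.2, 0), runif(4, 12, 12.2))
  d <- haversine_matrix(pts)
  S_gp <- gp_covariance(d, 0.5, 0.01)
  draws <- simulate_frailty(d, 0.5, 0.01, n = 20000, seed = 73)
  expect_lt(max(abs(cov(draws) - S_gp) / abs(S_gp)), 0.05)

  g3 <- path3_graph()
  S_car <- car_covariance(g3, 1.5, 0.6)
  draws_w <- simulate_regional_effects(g3, 1.5, 0.6, n = 1e5, seed = 74)
  expect_lt(max(abs(cov(draws_w) - S_car) / abs(S_car)), 0.05)
})

test_that("the log posterior equals the sum of independently computed parts", {
  m <- tiny_model(n = 12, adjust = "grp")
  set.seed(75)
  st <- initial_state(m)
  st$delta <- 0.8; st$beta <- rnorm(ncol(m$X), 0, 0.3); st$a <- -0.2
  st$w <- rnorm(2, 0, 0.5); st$phi <- rnorm(4, 0, 0.4)
  st$sigma2 <- 0.3; st$rho <- mean(m$priors$rho_support)
  st$sigmaq2 <- 0.7; st$gamma <- 0.4
  names(st$beta) <- colnames(m$X)

  reg_child <- m$region_of_cluster[m$cluster_idx]
  eta <- drop(m$X %*% st$beta) +
    (st$a + st$w[reg_child]) * m$z_region[reg_child] +
    st$phi[m$cluster_idx]
  loglik <- weibull_ph_loglik(m$time, m$event, eta, st$delta)
  lp_gp <- dmvnorm_log_ref(st$phi, gp_covariance(m$frame$distances,
                                                 st$sigma2, st$rho))
  lp_car <- dmvnorm_log_ref(st$w, car_covariance(m$graph, st$sigmaq2, st$gamma))
  ig <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
  pri <- ig(st$sigma2, 2.01, 1.01) + ig(st$sigmaq2, 2.01, 1.01) +
    dunif(st$rho, m$priors$rho_support[1], m$priors$rho_support[2], log = TRUE) +
    dunif(st$gamma, m$graph$gamma_bounds[1], m$graph$gamma_bounds[2], log = TRUE) +
    dexp(st$delta, 0.01, log = TRUE) +
    sum(dnorm(c(st$beta, st$a), 0, sqrt(1000), log = TRUE))

  expect_equal(log_posterior(st, m), loglik + lp_gp + lp_car + pri,
               tolerance = 1e-8)
})

test_that("states outside the prior support give -Inf, never an error", {
  m <- tiny_model()
  st <- initial_state(m)
  for (mod in list(list(delta = -1), list(sigma2 = 0),
                   list(gamma = 1.5), list(rho = 1e9))) {
    bad <- utils::modifyList(st, mod)
    expect_identical(log_posterior(bad, m), -Inf)
  }
})

test_that("a constant moved between intercept and frailties leaves eta fixed", {
  m <- tiny_model(adjust = "grp")
  st <- initial_state(m)
  st$phi <- rnorm(4); st$beta[1] <- -2
  shifted <- st
  shifted$phi <- st$phi + 0.7
  shifted$beta[1] <- st$beta[1] - 0.7
  expect_equal(svcsurv:::state_eta(st, m), svcsurv:::state_eta(shifted, m))
})

test_that("the inverse-gamma prior peaks at scale/(shape+1)", {
  xs <- seq(0.05, 2, by = 1e-4)
  dens <- vapply(xs, svcsurv:::dinvgamma_log, 0, shape = 2.01, scale = 1.01)
  expect_equal(xs[which.max(dens)], 1.01 / 3.01, tolerance = 1e-3)
})
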