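test_that("the shape-only reduction matches a dense-grid posterior", {
  # all blocks except delta fixed at eta = 0: the target is the Weibull
  # likelihood times the exponential(0.01) prior, integrable on a grid
  frame <- tiny_frame()
  set.seed(81)
  ch <- tibble::tibble(
    child_id = sprintf("k%d", 1:30),
    cluster_id = sample(frame$clusters$cluster_id, 30, replace = TRUE),
    time_months = pmax(rweibull(30, 0.8, 1), 0.05),
    event = rbinom(30, 1, 0.7))
  m <- svc_model(ch, frame, two_region_graph(), tiny_coverage(), "cov_x")
  base <- initial_state(m)
  fit <- svc_sample(
    m, mcmc_config(n_iterations = 30000, burn_in = 2000, thin = 5,
                   n_chains = 2, seed = 82),
    init = base[c("beta", "a", "w", "phi", "sigma2", "rho",
                  "sigmaq2", "gamma")],
    fix = c("beta", "w", "phi", "sigma_rho", "sigmaq_gamma"))
  d_draws <- pooled_draws(fit)[, "delta"]

  grid <- seq(1e-3, 5, length.out = 4000)
  log_post <- vapply(grid, function(dl) {
    sum(ch$event * log(dweibull(ch$time_months, dl, 1))) +
      sum((1 - ch$event) * pweibull(ch$time_months, dl, 1,
                                    lower.tail = FALSE, log.p = TRUE)) +
      dexp(dl, 0.01, log = TRUE)
  }, 0)
  wts <- exp(log_post - max(log_post))
  mean_ref <- sum(grid * wts) / sum(wts)
  expect_equal(mean(d_draws), mean_ref, tolerance = 0.02)
  # fixed blocks really stayed fixed
  expect_true(all(pooled_draws(fit)[, "a"] == 0))
  expect_true(all(pooled_draws(fit)[, "sigma2"] == 0.5))
})

test_that("identical seeds reproduce identical draws", {
  m <- tiny_model(n = 25, adjust = "grp")
  cfg <- mcmc_config(n_iterations = 400, burn_in = 100, thin = 2,
                     n_chains = 2, seed = 83)
  f1 <- svc_sample(m, cfg)
  f2 <- svc_sample(m, cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- svc_sample(m, mcmc_config(n_iterations = 400, burn_in = 100,
                                  thin = 2, n_chains = 2, seed = 84))
  expect_false(identical(f1$draws[[1]], f3$draws[[1]]))
})

test_that("all posterior draws respect the state invariants", {
  m <- tiny_model(n = 25, adjust = "grp")
  fit <- svc_sample(m, mcmc_config(n_iterations = 800, burn_in = 200,
                                   thin = 2, n_chains = 2, seed = 85))
  d <- pooled_draws(fit)
  expect_true(all(d[, "delta"] > 0))
  expect_true(all(d[, "sigma2"] > 0 & d[, "sigmaq2"] > 0))
  expect_true(all(d[, "rho"] > m$priors$rho_support[1] &
                    d[, "rho"] < m$priors$rho_support[2]))
  expect_true(all(d[, "gamma"] > m$graph$gamma_bounds[1] &
                    d[, "gamma"] < m$graph$gamma_bounds[2]))
  # acceptance bookkeeping is per block and sane
  for (a in fit$acceptance) expect_true(all(a >= 0 & a <= 1))
})

test_that("PSRF matches the closed form in the degenerate and extreme cases", {
  set.seed(86)
  x <- rnorm(500)
  # two identical chains: B = 0, PSRF = sqrt((n-1)/n) exactly
  expect_equal(unname(gelman_rubin(list(x, x))), sqrt(499 / 500),
               tolerance = 1e-12)
  # far-apart chains: plug the means into the formula by hand
  c1 <- rnorm(1000); c2 <- rnorm(1000, 10)
  expect_gt(unname(gelman_rubin(list(c1, c2))), 5)
  # random chains against an independently coded evaluation
  chains <- list(matrix(rnorm(600), 200), matrix(rnorm(600), 200))
  ref <- vapply(1:3, function(j) {
    xs <- cbind(chains[[1]][, j], chains[[2]][, j])
    n <- 200
    W <- mean(apply(xs, 2, var)); B <- n * var(colMeans(xs))
    sqrt(((n - 1) / n * W + (1 + 1 / 2) * B / n) / W)
  }, 0)
  expect_equal(unname(gelman_rubin(chains)), ref, tolerance = 1e-10)
  expect_error(gelman_rubin(list(x)), "2 chains")
})

test_that("posterior summaries use linear-interpolation quantiles", {
  # type-7 rule: h = 1 + (n-1)p, so for draws 1..100 the 2.5% point is
  # 1 + 99 * 0.025 = 3.475 and the 97.5% point is 1 + 99 * 0.975 = 97.525
  s <- summarize_draws(cbind(par = 1:100))
  expect_equal(s$median, 50.5)
  expect_equal(s$lower, 3.475)
  expect_equal(s$upper, 97.525)
  # quantile of exp equals exp of quantile when the rule lands on order
  # statistics (41 draws puts all three probes on integers)
  set.seed(87)
  x <- rnorm(41)
  s_raw <- summarize_draws(cbind(par = x))
  s_exp <- summarize_draws(cbind(par = exp(x)))
  expect_equal(s_exp$median, exp(s_raw$median), tolerance = 1e-12)
  expect_equal(s_exp$lower, exp(s_raw$lower), tolerance = 1e-12)
  expect_equal(s_exp$upper, exp(s_raw$upper), tolerance = 1e-12)
})

test_that("tidy and glance expose summaries and diagnostics", {
  m <- tiny_model(n = 25, adjust = "grp")
  fit <- svc_sample(m, mcmc_config(n_iterations = 600, burn_in = 100,
                                   thin = 2, n_chains = 2, seed = 88))
  td <- tidy(fit)
  expect_true(all(c("term", "median", "lower", "upper", "psrf") %in% names(td)))
  expect_true("delta" %in% td$term)
  th <- tidy(fit, exponentiate = TRUE)
  expect_equal(th$median[th$term == "a"],
               exp(td$median[td$term == "a"]), tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$n_chains, 2)
  expect_true(is.finite(gl$max_psrf_core))
})
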