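test_that("GP frailty draws have the advertised correlation structure", {
  # two clusters exactly one effective range apart: correlation 0.05
  frame_d <- matrix(c(0, 30, 30, 0), 2)
  rho <- svcsurv:::RANGE_CONST / 30
  draws <- simulate_frailty(frame_d, sigma2 = 1, rho = rho, n = 5000, seed = 31)
  expect_lt(abs(cor(draws[, 1], draws[, 2]) - 0.05), 0.04)
  # marginal variance
  expect_equal(unname(apply(draws, 2, var)), c(1, 1), tolerance = 0.05)

  # rho -> infinity limit: independence
  far <- simulate_frailty(matrix(c(0, 500, 500, 0), 2), 1, rho = 0.5,
                          n = 2000, seed = 32)
  expect_lt(abs(cor(far[, 1], far[, 2])), 0.05)
})

test_that("CAR regional draws match the closed-form covariance", {
  # gamma = 0, two regions with one neighbour each: covariance sigmaq2 * I
  g2 <- two_region_graph()
  d0 <- simulate_regional_effects(g2, sigmaq2 = 0.8, gamma = 0, n = 8000,
                                  seed = 33)
  expect_lt(abs(cor(d0[, 1], d0[, 2])), 0.05)
  expect_equal(unname(apply(d0, 2, var)), c(0.8, 0.8), tolerance = 0.05)

  # path graph, gamma = 0.5: empirical covariance vs direct 3x3 inverse,
  # entrywise relative error below 5%
  g3 <- path3_graph()
  S_ref <- 2 * solve(diag(3) - 0.5 * g3$C) %*% diag(g3$D, 3)
  d1 <- simulate_regional_effects(g3, 2, 0.5, n = 50000, seed = 34)
  expect_lt(max(abs(cov(d1) - S_ref) / abs(S_ref)), 0.05)
  # zero mean within 3 standard errors
  se <- sqrt(diag(S_ref) / 50000)
  expect_true(all(abs(colMeans(d1)) < 3 * se))

  expect_error(simulate_regional_effects(g2, 1, 1.5), "gamma")
})

test_that("survival-time draws follow the Weibull model", {
  # delta = 1, eta = 0: standard exponential
  t1 <- simulate_survival_times(rep(0, 1e5), 1, seed = 35)$time_months
  expect_equal(mean(t1), 1, tolerance = 0.02)
  # delta = 1, eta = log 2: exponential with rate 2
  t2 <- simulate_survival_times(rep(log(2), 1e5), 1, seed = 36)$time_months
  expect_equal(mean(t2), 0.5, tolerance = 0.02)
  # arbitrary (delta, eta): empirical CDF against the closed form
  for (par in list(c(0.5, -2), c(1.7, 0.3))) {
    delta <- par[1]; eta <- par[2]
    tt <- simulate_survival_times(rep(eta, 1e5), delta, seed = 37)$time_months
    for (q in quantile(tt, c(0.25, 0.5, 0.9))) {
      expect_equal(mean(tt <= q), 1 - exp(-q^delta * exp(eta)),
                   tolerance = 0.01)
    }
  }
  expect_error(simulate_survival_times(0, -1), "delta")
})

test_that("survey generation is deterministic and writes identical files", {
  cfg <- sim_config(n_clusters = 25, n_children = 300, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_survey(cfg, out_dir = d1)
  generate_survey(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("a protective intervention lowers mortality in high-coverage regions", {
  # strong effect, no spatial noise, coverage spread across a grid of regions
  g <- grid_region_graph(6)
  cov_tab <- tibble::tibble(region_id = g$region_ids,
                            x = seq(0.2, 0.9, length.out = 6))
  cfg <- sim_config(n_clusters = 30, n_children = 50000,
                    graph = g, coverage_by_region = cov_tab,
                    intervention = "x",
                    true_beta = c("(Intercept)" = -3.5),
                    covariate_marginals = list(),
                    true_a = log(0.8), true_sigma2 = 1e-4,
                    true_sigmaq2 = 1e-6, seed = 40)
  sv <- generate_survey(cfg)
  df <- sv$children |>
    dplyr::left_join(sv$clusters, by = "cluster_id") |>
    dplyr::group_by(region_id) |>
    dplyr::summarise(death = mean(event)) |>
    dplyr::left_join(cov_tab, by = "region_id")
  expect_lt(cor(df$x, df$death, method = "spearman"), -0.9)
})

test_that("the calibration preset yields a plausible DHS-like death fraction", {
  sv <- generate_survey(sim_config(seed = 12))
  df <- death_fraction(sv$children)
  expect_gte(df, 0.06)
  expect_lte(df, 0.12)
  # all invariants hold on the generated records
  expect_true(all(sv$children$time_months > 0 & sv$children$time_months <= 60))
  expect_true(all(sv$children$event %in% 0:1))
  expect_equal(nrow(sv$clusters), 541)
  expect_equal(nrow(sv$children), 13505)
})

test_that("with no noise the empirical KM curve matches the closed form", {
  g <- grid_region_graph(4)
  cov_tab <- tibble::tibble(region_id = g$region_ids, x = rep(0.6, 4))
  a_true <- log(0.85)
  cfg <- sim_config(n_clusters = 20, n_children = 1e5, graph = g,
                    coverage_by_region = cov_tab, intervention = "x",
                    true_beta = c("(Intercept)" = -4),
                    covariate_marginals = list(),
                    true_a = a_true, true_sigma2 = 1e-8, true_sigmaq2 = 1e-8,
                    true_delta = 0.5, seed = 41,
                    interview_window_months = 1e9)
  # no censoring before 60 months, so the KM curve is the empirical survivor
  sv <- generate_survey(cfg)
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = sv$children)
  eta <- -4 + a_true * 0.6 / 0.1
  for (t0 in c(12, 36, 60)) {
    s_km <- summary(fit, times = t0, extend = TRUE)$surv
    expect_equal(s_km, exp(-t0^0.5 * exp(eta)), tolerance = 0.01)
  }
})

test_that("censoring grows as the interview window shrinks", {
  cens_frac <- vapply(c(60, 30, 12), function(w) {
    cfg <- sim_config(n_clusters = 40, n_children = 20000,
                      interview_window_months = w, seed = 50)
    1 - mean(generate_survey(cfg)$children$event)
  }, 0)
  expect_true(all(diff(cens_frac) > 0))
})

test_that("config invariants are enforced before generation", {
  expect_error(sim_config(true_delta = -1), "true_delta")
  expect_error(sim_config(true_gamma = 2), "true_gamma")
  bad_marg <- default_covariate_marginals()
  bad_marg$sex <- c(female = 0.6, male = 0.6)
  expect_error(sim_config(covariate_marginals = bad_marg), "sum to 1")
  expect_error(sim_config(intervention = "nope"), "not in coverage")
})
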