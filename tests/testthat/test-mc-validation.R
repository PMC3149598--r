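test_that("simulated trials are reproducible and order-independent", {
  cfg <- sim_config(k = 5, m = 8, rho = 0.1, effect = effect_continuous(0.5),
                    n_sims = 10, seed = 42)
  expect_identical(simulate_trial(cfg, 3), simulate_trial(cfg, 3))
  expect_false(identical(simulate_trial(cfg, 3), simulate_trial(cfg, 4)))
  # replicate 3 is the same whether or not other replicates ran first
  first <- simulate_trial(cfg, 3)
  invisible(lapply(1:2, function(r) simulate_trial(cfg, r)))
  expect_identical(simulate_trial(cfg, 3), first)
  # the global RNG stream is not consumed
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_trial(cfg, 1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("continuous generator has the stated mean, variance and ICC", {
  # rho = 0: i.i.d. outcomes, sample ICC near 0
  cfg0 <- sim_config(k = 40, m = 25, rho = 0, effect = effect_continuous(0.3),
                     n_sims = 1, seed = 11)
  d0 <- simulate_trial(cfg0, 1)
  ctrl <- d0[d0$arm == "control", ]
  expect_lt(abs(oracle_icc_anova(ctrl$y, ctrl$cluster)), 0.05)

  # rho = 0.3: ANOVA ICC estimates average to 0.3 within MC error
  cfg <- sim_config(k = 50, m = 50, rho = 0.3, effect = effect_continuous(0),
                    n_sims = 1, seed = 12)
  iccs <- vapply(1:200, function(r) {
    d <- simulate_trial(cfg, r)
    d <- d[d$arm == "control", ]
    oracle_icc_anova(d$y, d$cluster)
  }, numeric(1))
  mc_se <- sd(iccs) / sqrt(length(iccs))
  expect_lt(abs(mean(iccs) - 0.3), 3 * mc_se)

  # intervention arm is shifted by d, total variance is sigma^2
  cfg_d <- sim_config(k = 60, m = 40, rho = 0.1,
                      effect = effect_continuous(0.8, sigma_sq = 2),
                      n_sims = 1, seed = 13)
  d <- simulate_trial(cfg_d, 1)
  gap <- mean(d$y[d$arm == "intervention"]) - mean(d$y[d$arm == "control"])
  expect_lt(abs(gap - 0.8), 0.15)
  expect_lt(abs(var(d$y[d$arm == "control"]) - 2), 0.4)
})

test_that("binary generator is beta-binomial with the right marginal mean", {
  cfg <- sim_config(k = 200, m = 50, rho = 0.1,
                    effect = effect_binary(0.3, 0.45), n_sims = 1, seed = 21)
  d <- simulate_trial(cfg, 1)
  expect_identical(nrow(d), 400L) # cluster-level rows
  expect_true(all(d$events >= 0 & d$events <= d$size))
  p_ctrl <- mean(d$p_hat[d$arm == "control"])
  p_int <- mean(d$p_hat[d$arm == "intervention"])
  expect_lt(abs(p_ctrl - 0.3), 0.03)
  expect_lt(abs(p_int - 0.45), 0.03)
  # between-cluster variance of true probabilities is rho * p(1-p);
  # the observed cluster proportions add binomial noise p(1-p)(1-rho)/m
  v_expect <- 0.1 * 0.3 * 0.7 + 0.3 * 0.7 * 0.9 / 50
  expect_lt(abs(var(d$p_hat[d$arm == "control"]) - v_expect),
            0.35 * v_expect)
  # rho = 0 collapses to plain binomial sampling
  cfg0 <- sim_config(k = 400, m = 20, rho = 0,
                     effect = effect_binary(0.3, 0.45), n_sims = 1, seed = 22)
  d0 <- simulate_trial(cfg0, 1)
  v0 <- var(d0$p_hat[d0$arm == "control"])
  expect_lt(abs(v0 - 0.3 * 0.7 / 20), 0.3 * (0.3 * 0.7 / 20))
})

test_that("null rejection rate is calibrated to alpha", {
  cfg <- sim_config(k = 50, m = 20, rho = 0.005,
                    effect = effect_continuous(0, sigma_sq = 0.245),
                    alpha = 0.05, n_sims = 1500, seed = 31)
  res <- empirical_power(cfg)
  se_null <- sqrt(0.05 * 0.95 / cfg$n_sims)
  expect_lt(abs(res$empirical_power - 0.05), 3 * se_null)
})

test_that("empirical power tracks the analytic cluster-trial formula", {
  cfg <- sim_config(k = 20, m = 22, rho = 0.005,
                    effect = effect_continuous(0.1, sigma_sq = 0.245),
                    alpha = 0.05, n_sims = 800, seed = 32)
  res <- empirical_power(cfg)
  expect_equal(res$analytic_power, 0.8135, tolerance = 1e-4)
  expect_lt(abs(res$z_discrepancy), 3)
  expect_true(res$mc_se > 0 && res$mc_se < 0.02)
})

test_that("empirical power grows with m and stays below the achievable maximum", {
  eff <- effect_binary(0.4, 0.52)
  map <- max_achievable_power(eff, 0.05, k = 20, rho = 0.07)
  powers <- vapply(c(20L, 200L, 2000L), function(m) {
    cfg <- sim_config(k = 20, m = m, rho = 0.07, effect = eff,
                      alpha = 0.05, n_sims = 500, seed = 33)
    empirical_power(cfg)$empirical_power
  }, numeric(1))
  expect_true(all(diff(powers) > 0))
  mc_se <- sqrt(map * (1 - map) / 500)
  expect_true(all(powers < map + 3 * mc_se))
  # at m = 2000 the empirical power is already close to the bound
  expect_gt(powers[3], map - 6 * mc_se)
})

test_that("simulation configs reject invalid designs", {
  expect_error(sim_config(k = 0, m = 10, rho = 0.1,
                          effect = effect_continuous(1)),
               class = "crctsize_domain_error")
  expect_error(sim_config(k = 5, m = 10, rho = 1,
                          effect = effect_continuous(1)),
               class = "crctsize_domain_error")
  expect_error(sim_config(k = 5, m = 10, rho = 0.1, effect = "binary"),
               class = "crctsize_domain_error")
  cfg <- sim_config(k = 5, m = 10, rho = 0.1, effect = effect_continuous(1))
  expect_error(simulate_trial(cfg, 0), class = "crctsize_domain_error")
})
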