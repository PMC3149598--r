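tp80 <- test_params(0.05, 0.8)
tp90 <- test_params(0.05, 0.9)
eff_10pt <- effect_binary(0.4, 0.5)

test_that("feasibility check reproduces the worked-example products", {
  low <- feasibility_check(eff_10pt, tp80, k = 20, rho = 0.005)
  expect_equal(low$product, 1.925, tolerance = 1e-12)
  expect_true(low$feasible)
  expect_equal(low$margin, 20 - 1.925, tolerance = 1e-12)

  high <- feasibility_check(eff_10pt, tp80, k = 20, rho = 0.07)
  expect_equal(high$product, 26.95, tolerance = 1e-12)
  expect_false(high$feasible)
  expect_false(high$feasible_if_equal)

  # 90% power: displayed product uses the integer n_I = 515
  expect_equal(feasibility_check(eff_10pt, tp90, k = 20, rho = 0.005)$product,
               515 * 0.005, tolerance = 1e-12)

  none <- feasibility_check(eff_10pt, tp80, k = 1, rho = 0)
  expect_identical(none$product, 0)
  expect_true(none$feasible)
})

test_that("relaxing cv to zero can only improve feasibility", {
  for (rho in c(0.01, 0.04, 0.07)) {
    rep_cv <- feasibility_check(eff_10pt, tp80, k = 20, rho = rho, cv = 0.65)
    expect_gte(rep_cv$feasible_if_equal, rep_cv$feasible)
  }
  # a design rescued by equal clusters: feasible at cv = 0 only
  resc <- feasibility_check(eff_10pt, tp80, k = 20, rho = 0.04, cv = 0.65)
  expect_false(resc$feasible)
  expect_true(resc$feasible_if_equal)
})

test_that("required cluster size reproduces all worked-example designs", {
  expect_identical(
    required_sample_size_fixed_k(eff_10pt, tp80, k = 20, rho = 0.005)$m, 22L
  )
  expect_identical(
    required_sample_size_fixed_k(eff_10pt, tp90, k = 20, rho = 0.005)$m, 30L
  )
  d80 <- required_sample_size_fixed_k(effect_binary(0.4, 0.52), tp80,
                                      k = 20, rho = 0.07)
  expect_identical(d80$m, 189L)
  expect_identical(d80$n_C, 3780L)
  d90 <- required_sample_size_fixed_k(effect_binary(0.4, 0.54), tp90,
                                      k = 20, rho = 0.07)
  expect_identical(d90$m, 146L)
  expect_identical(d90$n_C, 2920L)

  # brute-force power-scan oracle agrees on every case
  cases <- list(
    list(eff = eff_10pt, tp = tp80, rho = 0.005),
    list(eff = eff_10pt, tp = tp90, rho = 0.005),
    list(eff = effect_binary(0.4, 0.52), tp = tp80, rho = 0.07),
    list(eff = effect_binary(0.4, 0.54), tp = tp90, rho = 0.07)
  )
  for (cs in cases) {
    got <- required_sample_size_fixed_k(cs$eff, cs$tp, k = 20, rho = cs$rho)$m
    want <- oracle_fixed_k_m(cs$eff$d, cs$eff$sigma_sq, cs$tp$alpha,
                             cs$tp$power, k = 20, rho = cs$rho)
    expect_identical(got, as.integer(want))
  }
})

test_that("sample-size result satisfies its structural invariants", {
  grid <- expand.grid(k = c(6L, 20L, 41L), rho = c(0, 0.004, 0.01),
                      cv = c(0, 0.4))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- required_sample_size_fixed_k(eff_10pt, tp80, k = g$k,
                                        rho = g$rho, cv = g$cv)
    expect_identical(res$n_C, as.integer(g$k * res$m))
    expect_gte(res$n_C, res$n_C_raw)
    expect_lt(res$n_C - res$n_C_raw, g$k)
    expect_gte(res$n_C, res$n_I)
    expect_gte(res$n_C_raw, res$n_I_raw * (1 - g$rho)) # design effect never shrinks
    expect_identical(res$total, as.integer(2 * res$n_C))
    # achieved power meets the target; one fewer per cluster does not
    # (unless m-1 still covers the unrounded requirement)
    expect_gte(
      crct_power(eff_10pt, 0.05, k = g$k, m = res$m, rho = g$rho, cv = g$cv),
      0.8
    )
    if (res$m > 1 && g$k * (res$m - 1) < res$n_C_raw) {
      expect_lt(
        crct_power(eff_10pt, 0.05, k = g$k, m = res$m - 1,
                   rho = g$rho, cv = g$cv),
        0.8
      )
    }
  }
})

test_that("rho = 0 reduces to plain rounding of the individual size", {
  res <- required_sample_size_fixed_k(eff_10pt, tp80, k = 20, rho = 0)
  expect_identical(res$m, as.integer(ceiling(res$n_I_raw / 20)))
  expect_identical(res$n_C, as.integer(20 * ceiling(res$n_I_raw / 20)))
})

test_that("required clusters for fixed m matches hand arithmetic and inverts", {
  expect_identical(
    required_clusters_fixed_m(eff_10pt, tp80, m = 22, rho = 0.005), 20L
  )
  expect_identical(
    required_clusters_fixed_m(eff_10pt, tp80, m = 50, rho = 0.07), 35L
  )
  # m = 1, rho = 0: one individual per cluster, k = n_I
  expect_identical(
    required_clusters_fixed_m(eff_10pt, tp80, m = 1, rho = 0), 385L
  )
  # inversion: the k' needed at the returned m never exceeds k
  for (rho in c(0.001, 0.005, 0.02)) {
    m <- required_sample_size_fixed_k(eff_10pt, tp80, k = 20, rho = rho)$m
    expect_lte(required_clusters_fixed_m(eff_10pt, tp80, m = m, rho = rho), 20L)
  }
})

test_that("cluster size diverges monotonically towards the feasibility boundary", {
  # boundary in rho for this effect and k = 20: n_I_raw * rho = 20
  n_raw <- rct_sample_size(eff_10pt, tp80)$n_raw
  rho_star <- 20 / n_raw
  rhos <- rho_star * c(0.5, 0.9, 0.99, 0.999, 0.9999)
  ms <- sapply(rhos, function(r) {
    required_sample_size_fixed_k(eff_10pt, tp80, k = 20, rho = r)$m
  })
  expect_true(all(diff(ms) > 0))
  expect_gt(ms[length(ms)], 1e5)

  # at and above the boundary: structured error carrying the report
  for (r in c(rho_star, rho_star * 1.01)) {
    err <- expect_error(
      required_sample_size_fixed_k(eff_10pt, tp80, k = 20, rho = r),
      class = "crctsize_infeasible_error"
    )
    expect_s3_class(err$report, "crct_feasibility")
    expect_false(err$report$feasible)
  }
})
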