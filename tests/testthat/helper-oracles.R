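# Independent oracles used across tests. These deliberately re-derive
# quantities by a different route than the package (brute force, base-R
# model fits, polyroot) so the two can disagree.

# One-way ANOVA estimator of the intra-cluster correlation for
# individual-level continuous data.
oracle_icc_anova <- function(y, cluster) {
  fit <- anova(lm(y ~ factor(cluster)))
  msb <- fit["factor(cluster)", "Mean Sq"]
  msw <- fit["Residuals", "Mean Sq"]
  m <- length(y) / length(unique(cluster))
  (msb - msw) / (msb + (m - 1) * msw)
}

# Roots of a * x^2 + b * x + c via base R's polynomial solver.
oracle_quadratic_roots <- function(a, b, c) {
  sort(Re(polyroot(c(c, b, a))))
}

# Brute-force per-arm sample size: smallest integer n whose analytic power
# reaches the target (linear scan from 2).
oracle_rct_n <- function(d, sigma_sq, alpha, power) {
  z_crit <- qnorm(1 - alpha / 2)
  n <- 2L
  while (pnorm(abs(d) * sqrt(n / (2 * sigma_sq)) - z_crit) < power) {
    n <- n + 1L
  }
  n
}

# Brute-force per-cluster size for fixed k: smallest m (in whole clusters,
# i.e. n_C a multiple of k) whose cluster-trial power reaches the target.
# Returns NA when no m up to m_max works.
oracle_fixed_k_m <- function(d, sigma_sq, alpha, power, k, rho, m_max = 10000) {
  z_crit <- qnorm(1 - alpha / 2)
  for (m in seq_len(m_max)) {
    infl <- 1 + (m - 1) * rho
    p <- pnorm(abs(d) * sqrt(k * m / (2 * sigma_sq * infl)) - z_crit)
    if (p >= power) return(m)
  }
  NA_integer_
}
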