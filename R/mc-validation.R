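#' Configuration for a Monte-Carlo power simulation
#'
#' Bundles the design (k clusters per arm of size m, ICC rho), the effect,
#' the test size and the simulation settings. The data-generating model is
#' chosen so the intra-cluster correlation is exactly `rho`:
#'
#' * continuous outcomes: a shared cluster effect with variance
#'   \eqn{\rho\sigma^2} plus individual noise with variance
#'   \eqn{(1-\rho)\sigma^2} (total variance \eqn{\sigma^2});
#' * binary outcomes: cluster-level event probabilities drawn from a beta
#'   distribution with mean \eqn{\pi} and shape sum \eqn{(1-\rho)/\rho}
#'   (so the ICC on the proportion scale is \eqn{\rho}), then binomial
#'   counts — the beta-binomial model.
#'
#' @param k Clusters per arm.
#' @param m Individuals per cluster (equal sizes; the analytic comparator
#'   is the equal-cluster power formula).
#' @param rho Intra-cluster correlation in [0, 1).
#' @param effect An [effect_continuous()] or [effect_binary()] object.
#' @param alpha Two-sided significance level. Default 0.05.
#' @param n_sims Number of simulated trials. Default 1000.
#' @param seed Master seed; every replicate derives its own substream from
#'   it, so results do not depend on execution order.
#'
#' @return An object of class `"sim_config"`.
#' @examples
#' sim_config(k = 20, m = 22, rho = 0.005,
#'            effect = effect_continuous(0.1, sigma_sq = 0.245), seed = 1)
#' @export
sim_config <- function(k, m, rho, effect, alpha = 0.05, n_sims = 1000,
                       seed = 1L) {
  k <- check_count(k, "k")
  m <- check_count(m, "m")
  check_icc(rho)
  effect <- as_effect_spec(effect)
  check_probability(alpha, "alpha")
  n_sims <- check_count(n_sims, "n_sims")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_domain("`seed` must be a single integer.")
  }
  structure(
    list(k = k, m = m, rho = rho, effect = effect, alpha = alpha,
         n_sims = n_sims, seed = as.numeric(seed)),
    class = "sim_config"
  )
}

# Counter-derived substream seed: a distinct, reproducible seed for each
# replicate, independent of the order replicates are run in. Linear
# congruential mix kept within exact double-precision integer range.
replicate_seed <- function(seed, replicate_index) {
  as.integer((abs(seed) %% 2147483647 * 48271 + replicate_index * 30269) %%
               2147483647) + 1L
}

#' Simulate one cluster randomised trial
#'
#' Generates a single two-arm trial under the model described in
#' [sim_config()]. Deterministic given `(config$seed, replicate_index)`;
#' the global RNG state is left untouched.
#'
#' @param config A [sim_config()] object.
#' @param replicate_index Positive integer identifying the replicate.
#' @return For continuous outcomes, a tibble with one row per individual
#'   (`arm`, `cluster`, `y`). For binary outcomes, a tibble with one row
#'   per cluster (`arm`, `cluster`, `size`, `events`, `p_hat`) — the
#'   cluster-mean analysis needs nothing finer.
#' @examples
#' cfg <- sim_config(k = 5, m = 10, rho = 0.1,
#'                   effect = effect_continuous(0.5), seed = 42)
#' simulate_trial(cfg, 1)
#' @export
simulate_trial <- function(config, replicate_index) {
  if (!inherits(config, "sim_config")) {
    stop_domain("`config` must be created with `sim_config()`.")
  }
  replicate_index <- check_count(replicate_index, "replicate_index")
  withr::with_seed(
    replicate_seed(config$seed, replicate_index),
    generate_trial_data(config)
  )
}

generate_trial_data <- function(config) {
  k <- config$k
  m <- config$m
  rho <- config$rho
  eff <- config$effect
  if (eff$kind == "continuous") {
    arm_means <- c(control = 0, intervention = eff$d)
    purrr::map_dfr(names(arm_means), function(arm) {
      mu <- arm_means[[arm]]
      cluster_effect <- rnorm(k, 0, sqrt(rho * eff$sigma_sq))
      tibble(
        arm = arm,
        cluster = rep(seq_len(k), each = m),
        y = mu + rep(cluster_effect, each = m) +
          rnorm(k * m, 0, sqrt((1 - rho) * eff$sigma_sq))
      )
    })
  } else {
    arm_pi <- c(control = eff$pi1, intervention = eff$pi2)
    purrr::map_dfr(names(arm_pi), function(arm) {
      p <- arm_pi[[arm]]
      prob <- if (rho > 0) {
        rbeta(k, p * (1 - rho) / rho, (1 - p) * (1 - rho) / rho)
      } else {
        rep(p, k)
      }
      events <- rbinom(k, m, prob)
      tibble(
        arm = arm, cluster = seq_len(k), size = m,
        events = events, p_hat = events / m
      )
    })
  }
}

# Two-sample z-test on cluster means: the analysis whose variance model
# matches the normal-theory power formulas. Returns TRUE when the null is
# rejected at two-sided level alpha.
cluster_mean_test <- function(data, alpha) {
  if ("y" %in% names(data)) {
    means <- tapply(data$y, list(data$arm, data$cluster), mean)
  } else {
    means <- tapply(data$p_hat, list(data$arm, data$cluster), mean)
  }
  m0 <- means["control", ]
  m1 <- means["intervention", ]
  se <- sqrt(var(m1) / length(m1) + var(m0) / length(m0))
  abs(mean(m1) - mean(m0)) / se > qnorm(1 - alpha / 2)
}

#' Empirical power of the cluster-mean analysis by simulation
#'
#' Simulates `config$n_sims` trials, analyses each with a two-sample
#' z-test on cluster means (two-sided at `config$alpha`), and compares the
#' rejection proportion with the analytic cluster-trial power
#' ([crct_power()]) for the same design. The Monte-Carlo standard error is
#' \eqn{\sqrt{\hat p(1-\hat p)/n_{sims}}} and `z_discrepancy` expresses
#' the empirical-minus-analytic gap in units of that standard error.
#'
#' @param config A [sim_config()] object.
#' @return A one-row tibble of class `"crct_simulation"`: the design
#'   parameters plus `empirical_power`, `mc_se`, `analytic_power` and
#'   `z_discrepancy`.
#' @examples
#' cfg <- sim_config(k = 10, m = 10, rho = 0.02,
#'                   effect = effect_continuous(0.5), n_sims = 200, seed = 7)
#' empirical_power(cfg)
#' @export
empirical_power <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_domain("`config` must be created with `sim_config()`.")
  }
  rejected <- purrr::map_lgl(
    seq_len(config$n_sims),
    function(r) cluster_mean_test(simulate_trial(config, r), config$alpha)
  )
  p_hat <- mean(rejected)
  analytic <- crct_power(config$effect, config$alpha,
                         k = config$k, m = config$m, rho = config$rho)
  mc_se <- sqrt(p_hat * (1 - p_hat) / config$n_sims)
  out <- tibble(
    kind = config$effect$kind,
    d = config$effect$d,
    sigma_sq = config$effect$sigma_sq,
    k = config$k, m = config$m, rho = config$rho,
    alpha = config$alpha, n_sims = config$n_sims, seed = config$seed,
    empirical_power = p_hat,
    mc_se = mc_se,
    analytic_power = analytic,
    z_discrepancy = if (mc_se > 0) (p_hat - analytic) / mc_se else
      if (p_hat == analytic) 0 else Inf * sign(p_hat - analytic)
  )
  class(out) <- c("crct_simulation", class(out))
  out
}

#' Plot empirical against analytic power for simulation results
#'
#' @param object A `"crct_simulation"` tibble (one or more rows, e.g.
#'   several scenarios bound together).
#' @param ... Unused.
#' @return A ggplot: analytic power on the x axis, empirical power with
#'   approximate 95% Monte-Carlo error bars on the y axis, and the
#'   identity line.
#' @exportS3Method ggplot2::autoplot
autoplot.crct_simulation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$analytic_power,
                                       y = .data$empirical_power)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$empirical_power - 1.96 * .data$mc_se),
                   ymax = pmin(1, .data$empirical_power + 1.96 * .data$mc_se)),
      width = 0
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Analytic power (cluster-trial normal approximation)",
      y = "Empirical power (cluster-mean z-test)",
      title = "Monte-Carlo validation of the analytic power formula"
    )
}
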