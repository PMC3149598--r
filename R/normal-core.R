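#' Standard-normal quantile with domain checking
#'
#' Thin wrapper around [stats::qnorm()] that rejects probabilities outside
#' the open interval (0, 1). Used for \eqn{z_{\alpha/2}} and \eqn{z_\beta}.
#'
#' @param p Probability in (0, 1).
#' @return \eqn{\Phi^{-1}(p)} at full double precision.
#' @examples
#' z_quantile(0.975)
#' @export
z_quantile <- function(p) {
  check_probability(p, "p")
  qnorm(p)
}

#' Standard-normal cumulative distribution function
#'
#' @param x Real number (vectorised).
#' @return \eqn{\Phi(x)}.
#' @examples
#' normal_cdf(1.959964)
#' @export
normal_cdf <- function(x) {
  if (!is.numeric(x)) stop_domain("`x` must be numeric.")
  pnorm(x)
}

#' Pooled variance approximation for a difference of two proportions
#'
#' The normal-approximation variance used for binary outcomes throughout:
#' \deqn{\sigma^2 = \frac{\pi_1(1-\pi_1) + \pi_2(1-\pi_2)}{2}.}
#' An unpooled (Fleiss-style) variance is deliberately not offered; mixing
#' conventions changes borderline sample sizes (vignette, "Known
#' inconsistencies").
#'
#' @param pi1,pi2 Proportions in (0, 1).
#' @return The pooled variance.
#' @examples
#' binary_pooled_variance(0.4, 0.5) # 0.245
#' @export
binary_pooled_variance <- function(pi1, pi2) {
  check_probability(pi1, "pi1")
  check_probability(pi2, "pi2")
  (pi1 * (1 - pi1) + pi2 * (1 - pi2)) / 2
}

#' Per-arm sample size under individual randomisation
#'
#' The baseline two-sample normal-approximation sample size
#' \deqn{n_I = (z_{\alpha/2} + z_\beta)^2 \, 2\sigma^2 / d^2,}
#' reported both unrounded (`n_raw`) and rounded up (`n`). The unrounded
#' value is what the fixed-cluster formulas consume: carrying the integer
#' forward changes the published per-cluster sizes for strongly clustered
#' designs (see [required_sample_size_fixed_k()]).
#'
#' @param effect An [effect_continuous()] or [effect_binary()] object.
#' @param test A [test_params()] object.
#'
#' @return A one-row tibble with columns `n_raw` and `n`.
#' @examples
#' rct_sample_size(effect_binary(0.4, 0.5), test_params(0.05, 0.8)) # n = 385
#' @export
rct_sample_size <- function(effect, test) {
  effect <- as_effect_spec(effect)
  test <- as_test_params(test)
  if (effect$d == 0) {
    stop_domain("Cannot size a trial for a zero difference (`d` = 0).")
  }
  n_raw <- (test$z_alpha_half + test$z_beta)^2 * 2 * effect$sigma_sq / effect$d^2
  tibble(n_raw = n_raw, n = as.integer(ceiling(n_raw)))
}

#' Detectable difference under individual randomisation
#'
#' The difference detectable with `n` individuals per arm at the stated
#' significance level and power:
#' \deqn{d_I = (z_{\alpha/2} + z_\beta)\sqrt{2\sigma^2/n}.}
#'
#' @param n Individuals per arm (need not be an integer; >= 1).
#' @param sigma_sq Outcome variance.
#' @param test A [test_params()] object.
#' @return The detectable difference (positive scale).
#' @examples
#' rct_detectable_difference(385, 0.245, test_params(0.05, 0.8))
#' @export
rct_detectable_difference <- function(n, sigma_sq, test) {
  test <- as_test_params(test)
  check_positive(sigma_sq, "sigma_sq")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop_domain("`n` must be a single number >= 1.")
  }
  (test$z_alpha_half + test$z_beta) * sqrt(2 * sigma_sq / n)
}

#' Power under individual randomisation
#'
#' Two-sided normal-approximation power for a difference `d` with `n`
#' individuals per arm:
#' \deqn{1-\beta = \Phi\left(|d|\sqrt{n/(2\sigma^2)} - z_{\alpha/2}\right).}
#' The opposite-tail term \eqn{\Phi(-|d|\sqrt{n/2\sigma^2} - z_{\alpha/2})}
#' is omitted, as is conventional (it is negligible except at `d` near 0,
#' where the formula returns \eqn{\alpha/2} rather than \eqn{\alpha}).
#'
#' @param n Individuals per arm (>= 1).
#' @param effect An effect specification.
#' @param alpha Two-sided significance level.
#' @return Power, a probability.
#' @examples
#' rct_power(385, effect_binary(0.4, 0.5), alpha = 0.05)
#' @export
rct_power <- function(n, effect, alpha = 0.05) {
  effect <- as_effect_spec(effect)
  check_probability(alpha, "alpha")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop_domain("`n` must be a single number >= 1.")
  }
  pnorm(abs(effect$d) * sqrt(n / (2 * effect$sigma_sq)) - qnorm(1 - alpha / 2))
}
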