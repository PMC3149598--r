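#' Detectable difference in a cluster trial of fixed size
#'
#' For `k` clusters per arm each of (average) size `m`, the detectable
#' difference is the individually-randomised one at `n = k m`, inflated by
#' the square root of the variance inflation factor:
#' \deqn{d_C = (z_{\alpha/2}+z_\beta)\sqrt{2\sigma^2\,VIF/(km)}.}
#'
#' @param sigma_sq Outcome variance.
#' @param test A [test_params()] object.
#' @param k Clusters per arm.
#' @param m Individuals per cluster (average when `cv > 0`).
#' @param rho Intra-cluster correlation in [0, 1).
#' @param cv Coefficient of variation of cluster sizes, >= 0.
#' @return The detectable difference.
#' @examples
#' crct_detectable_difference(0.245, test_params(), k = 20, m = 22, rho = 0.005)
#' @export
crct_detectable_difference <- function(sigma_sq, test, k, m, rho, cv = 0) {
  test <- as_test_params(test)
  check_count(k, "k")
  rct_detectable_difference(k * m, sigma_sq, test) * sqrt(vif(m, rho, cv))
}

#' Power of a cluster trial of fixed size
#'
#' Power under individual randomisation with the standardised effect size
#' deflated by the square root of the variance inflation factor:
#' \deqn{1-\beta_C = \Phi\!\left(|d|\sqrt{\frac{km}{2\sigma^2\,VIF}} -
#'   z_{\alpha/2}\right).}
#' `|d|` is used so that swapping arm labels never changes the result.
#' Strictly below [max_achievable_power()] for every finite `m`, and
#' converging to it as `m` grows.
#'
#' @param effect An effect specification.
#' @param alpha Two-sided significance level.
#' @inheritParams crct_detectable_difference
#' @return Power, a probability.
#' @examples
#' crct_power(effect_binary(0.4, 0.5), alpha = 0.05, k = 20, m = 22, rho = 0.005)
#' @export
crct_power <- function(effect, alpha = 0.05, k, m, rho, cv = 0) {
  effect <- as_effect_spec(effect)
  check_probability(alpha, "alpha")
  check_count(k, "k")
  inflation <- vif(m, rho, cv)
  pnorm(
    abs(effect$d) * sqrt(k * m / (2 * effect$sigma_sq * inflation)) -
      qnorm(1 - alpha / 2)
  )
}
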