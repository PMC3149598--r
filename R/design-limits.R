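#' Minimum detectable difference (continuous outcome) for fixed clusters
#'
#' The smallest difference detectable at the stated power with `k`
#' clusters per arm, in the limit of infinitely large clusters:
#' \deqn{d_{MDD} = (z_{\alpha/2}+z_\beta)\sqrt{2\sigma^2\rho(cv^2+1)/k}.}
#' Any target difference at or below this value is undetectable at the
#' target power no matter how many individuals each cluster enrols.
#' Returns 0 when `rho = 0` (no precision floor).
#'
#' @param sigma_sq Outcome variance.
#' @param test A [test_params()] object.
#' @param k Clusters per arm.
#' @param rho Intra-cluster correlation in [0, 1).
#' @param cv Coefficient of variation of cluster sizes, >= 0.
#' @return The minimum detectable difference.
#' @examples
#' mdd_continuous(1, test_params(0.05, 0.8), k = 10, rho = 0.02)
#' @export
mdd_continuous <- function(sigma_sq, test, k, rho, cv = 0) {
  test <- as_test_params(test)
  (test$z_alpha_half + test$z_beta) *
    sqrt(precision_bound_variance(sigma_sq, k, rho, cv))
}

#' Minimum detectable difference (binary outcome) for fixed clusters
#'
#' For a fixed control proportion \eqn{\pi_1}, the limiting detectable
#' intervention proportion \eqn{\pi_2} solves
#' \deqn{d^2 = (\pi_2-\pi_1)^2 = w\,\big(\pi_1(1-\pi_1) +
#'   \pi_2(1-\pi_2)\big), \qquad w = \rho\,(cv^2+1)\,
#'   (z_{\alpha/2}+z_\beta)^2/k,}
#' i.e. the pooled variance is evaluated at the root itself. Expanding
#' gives the quadratic \eqn{a\pi_2^2 + b\pi_2 + c = 0} with
#' \deqn{a = -(1+w),\quad b = 2\pi_1 + w,\quad c = w\pi_1 - \pi_1^2(1+w).}
#' The two roots bracket \eqn{\pi_1}: the upper root is the limit for an
#' increase, the lower for a decrease. The headline MDD is
#' `pi2_upper - pi1`, reported raw and rounded *up* at two decimals
#' (rounding down would overstate what the design can detect).
#'
#' @param pi1 Control proportion in (0, 1).
#' @inheritParams mdd_continuous
#' @return A one-row tibble of class `"crct_mdd"` with columns `w`, `a`,
#'   `b`, `c` (quadratic coefficients), `pi2_lower`, `pi2_upper`, `d_mdd`
#'   and `d_mdd_rounded`.
#' @examples
#' mdd_binary(0.4, test_params(0.05, 0.8), k = 20, rho = 0.07)
#' @export
mdd_binary <- function(pi1, test, k, rho, cv = 0) {
  check_probability(pi1, "pi1")
  test <- as_test_params(test)
  k <- check_count(k, "k")
  check_icc(rho)
  check_positive(cv, "cv", strict = FALSE)

  w <- rho * (cv^2 + 1) * (test$z_alpha_half + test$z_beta)^2 / k
  if (w == 0) {
    # No precision floor: the quadratic degenerates to a double root at
    # pi1 and the minimum detectable difference is 0.
    out <- tibble(
      w = 0, a = -1, b = 2 * pi1, c = -pi1^2,
      pi2_lower = pi1, pi2_upper = pi1, d_mdd = 0, d_mdd_rounded = 0
    )
    class(out) <- c("crct_mdd", class(out))
    return(out)
  }
  a <- -(1 + w)
  b <- 2 * pi1 + w
  cc <- w * pi1 - pi1^2 * (1 + w)
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) {
    abort(
      sprintf(
        "No finite minimum detectable difference: the quadratic in pi2 has no real roots (discriminant %.4g; pi1 = %g, w = %.4g).",
        disc, pi1, w
      ),
      class = "crctsize_infeasible_error"
    )
  }
  roots <- sort(c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a)))
  if (roots[1] <= 0 || roots[2] >= 1) {
    abort(
      sprintf(
        "No feasible minimum detectable difference: roots %.4g and %.4g fall outside (0, 1) (pi1 = %g, w = %.4g). The baseline proportion is too extreme for this k and ICC.",
        roots[1], roots[2], pi1, w
      ),
      class = "crctsize_infeasible_error"
    )
  }

  d_mdd <- roots[2] - pi1
  out <- tibble(
    w = w, a = a, b = b, c = cc,
    pi2_lower = roots[1], pi2_upper = roots[2],
    d_mdd = d_mdd,
    d_mdd_rounded = ceiling_2dp(d_mdd)
  )
  class(out) <- c("crct_mdd", class(out))
  out
}

#' Maximum achievable power for a fixed number of clusters
#'
#' The supremum of [crct_power()] over the cluster size: with the
#' precision floor \eqn{2\sigma^2\rho(cv^2+1)/k},
#' \deqn{1-\beta_{MAP} = \Phi\!\left(\frac{|d|}
#'   {\sqrt{2\sigma^2\rho(cv^2+1)/k}} - z_{\alpha/2}\right).}
#' This bound is approached, never attained, at finite cluster sizes.
#' With `rho = 0` it is 1 for any non-zero difference; with `d = 0` it is
#' \eqn{\alpha/2}.
#'
#' @param effect An effect specification.
#' @param alpha Two-sided significance level.
#' @inheritParams mdd_continuous
#' @return The maximum achievable power, a probability.
#' @examples
#' max_achievable_power(effect_binary(0.4, 0.5), alpha = 0.05, k = 15, rho = 0.05)
#' @export
max_achievable_power <- function(effect, alpha = 0.05, k, rho, cv = 0) {
  effect <- as_effect_spec(effect)
  check_probability(alpha, "alpha")
  k <- check_count(k, "k")
  check_icc(rho)
  check_positive(cv, "cv", strict = FALSE)
  if (rho == 0) {
    return(if (effect$d == 0) alpha / 2 else 1)
  }
  bound <- precision_bound_variance(effect$sigma_sq, k, rho, cv)
  pnorm(abs(effect$d) / sqrt(bound) - qnorm(1 - alpha / 2))
}
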