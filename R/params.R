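#' Significance level and target power for a two-sided test
#'
#' Bundles the two-sided significance level \eqn{\alpha} and the target
#' power \eqn{1-\beta} together with the standard-normal quantiles
#' \eqn{z_{\alpha/2} = \Phi^{-1}(1-\alpha/2)} and
#' \eqn{z_\beta = \Phi^{-1}(1-\beta)} that all the sample-size formulas
#' are built from. Quantiles are kept at full double precision: the
#' two-decimal textbook values 1.96 / 0.84 shift borderline sample sizes
#' (see the methods vignette).
#'
#' @param alpha Two-sided significance level, in (0, 1). Default 0.05.
#' @param power Target power \eqn{1-\beta}, in (0, 1). Default 0.8.
#'
#' @return An object of class `"test_params"`: a list with elements
#'   `alpha`, `power`, `z_alpha_half` and `z_beta`.
#' @examples
#' test_params(0.05, 0.9)
#' @export
test_params <- function(alpha = 0.05, power = 0.8) {
  check_probability(alpha, "alpha")
  check_probability(power, "power")
  structure(
    list(
      alpha = alpha,
      power = power,
      z_alpha_half = qnorm(1 - alpha / 2),
      z_beta = qnorm(power)
    ),
    class = "test_params"
  )
}

#' @export
print.test_params <- function(x, ...) {
  cat(sprintf(
    "Two-sided test: alpha = %g (z = %.6f), power = %g (z = %.6f)\n",
    x$alpha, x$z_alpha_half, x$power, x$z_beta
  ))
  invisible(x)
}

#' Effect specification for a continuous outcome
#'
#' The difference in means `d` to detect and the common outcome variance
#' \eqn{\sigma^2}. Either `sd` or `sigma_sq` may be given. With `sd = 1`,
#' `d` is a standardised effect size.
#'
#' @param d Difference in means to detect (may be negative; sample-size
#'   formulas use `|d|`).
#' @param sd Outcome standard deviation \eqn{\sigma > 0}. Default 1.
#' @param sigma_sq Outcome variance \eqn{\sigma^2}; overrides `sd` when given.
#'
#' @return An object of class `c("effect_continuous", "effect_spec")` with
#'   elements `kind`, `d` and `sigma_sq`.
#' @examples
#' effect_continuous(0.2)            # standardised effect size 0.2
#' effect_continuous(5, sd = 12)     # 5-unit shift, sd 12
#' @export
effect_continuous <- function(d, sd = 1, sigma_sq = NULL) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d)) {
    stop_domain("`d` must be a single number.")
  }
  if (is.null(sigma_sq)) {
    check_positive(sd, "sd")
    sigma_sq <- sd^2
  } else {
    check_positive(sigma_sq, "sigma_sq")
  }
  structure(
    list(kind = "continuous", d = d, sigma_sq = sigma_sq),
    class = c("effect_continuous", "effect_spec")
  )
}

#' Effect specification for a binary outcome
#'
#' Control and intervention proportions \eqn{\pi_1, \pi_2}. The difference
#' is \eqn{d = \pi_2 - \pi_1} and the variance is the pooled
#' normal-approximation value
#' \eqn{\sigma^2 = (\pi_1(1-\pi_1) + \pi_2(1-\pi_2))/2}
#' (see [binary_pooled_variance()]), used consistently throughout.
#'
#' @param pi1,pi2 Control and intervention proportions, each in (0, 1),
#'   with `pi1 != pi2`.
#'
#' @return An object of class `c("effect_binary", "effect_spec")` with
#'   elements `kind`, `pi1`, `pi2`, `d` and `sigma_sq`.
#' @examples
#' effect_binary(0.4, 0.5)
#' @export
effect_binary <- function(pi1, pi2) {
  check_probability(pi1, "pi1")
  check_probability(pi2, "pi2")
  if (pi1 == pi2) {
    stop_domain("`pi1` and `pi2` must differ: a zero difference has no finite sample size.")
  }
  structure(
    list(
      kind = "binary",
      pi1 = pi1,
      pi2 = pi2,
      d = pi2 - pi1,
      sigma_sq = binary_pooled_variance(pi1, pi2)
    ),
    class = c("effect_binary", "effect_spec")
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  if (x$kind == "binary") {
    cat(sprintf(
      "Binary effect: pi1 = %g, pi2 = %g (d = %g, pooled sigma^2 = %g)\n",
      x$pi1, x$pi2, x$d, x$sigma_sq
    ))
  } else {
    cat(sprintf("Continuous effect: d = %g, sigma^2 = %g\n", x$d, x$sigma_sq))
  }
  invisible(x)
}

as_effect_spec <- function(effect) {
  if (!inherits(effect, "effect_spec")) {
    stop_domain(
      "`effect` must be created with `effect_continuous()` or `effect_binary()`."
    )
  }
  effect
}

as_test_params <- function(test) {
  if (!inherits(test, "test_params")) {
    stop_domain("`test` must be created with `test_params()`.")
  }
  test
}
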