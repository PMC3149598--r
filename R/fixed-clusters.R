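#' Feasibility check for a fixed number of clusters
#'
#' A design with `k` clusters per arm can reach the target power for the
#' stated effect only if
#' \deqn{k > n_I\,\rho\,(cv^2+1),}
#' where \eqn{n_I} is the per-arm size under individual randomisation:
#' beyond that point no cluster size, however large, recovers the lost
#' precision. Equality is infeasible (it corresponds to infinitely large
#' clusters).
#'
#' The displayed `product` uses the integer \eqn{n_I} (matching how the
#' check is usually quoted); the `feasible` flag uses the unrounded
#' \eqn{n_I} so that the boolean agrees exactly with the divergence point
#' of [required_sample_size_fixed_k()]. The two can disagree only in a
#' razor-thin band at the boundary, where the unrounded check is the
#' conservative one.
#'
#' @param effect An [effect_continuous()] or [effect_binary()] object.
#' @param test A [test_params()] object.
#' @param k Clusters per arm.
#' @param rho Intra-cluster correlation in [0, 1).
#' @param cv Coefficient of variation of cluster sizes, >= 0.
#'
#' @return A one-row tibble of class `"crct_feasibility"` with columns
#'   `product` (\eqn{n_I \rho (cv^2+1)} at integer \eqn{n_I}), `k`,
#'   `feasible`, `margin` (`k - product`) and `feasible_if_equal`
#'   (the same check at `cv = 0`).
#' @examples
#' feasibility_check(effect_binary(0.4, 0.5), test_params(), k = 20, rho = 0.005)
#' feasibility_check(effect_binary(0.4, 0.5), test_params(), k = 20, rho = 0.07)
#' @export
feasibility_check <- function(effect, test, k, rho, cv = 0) {
  effect <- as_effect_spec(effect)
  test <- as_test_params(test)
  k <- check_count(k, "k")
  check_icc(rho)
  check_positive(cv, "cv", strict = FALSE)

  size <- rct_sample_size(effect, test)
  product_display <- size$n * rho * (cv^2 + 1)
  product_raw <- size$n_raw * rho * (cv^2 + 1)

  out <- tibble(
    product = product_display,
    k = k,
    feasible = product_raw < k,
    margin = k - product_display,
    feasible_if_equal = size$n_raw * rho < k
  )
  class(out) <- c("crct_feasibility", class(out))
  out
}

#' Required cluster size when the number of clusters is fixed
#'
#' The central calculation for designs in which `k` clusters per arm are
#' available and the cluster size must be found. Substituting `m = n_C/k`
#' into the design-effect-inflated sample size and solving gives the
#' closed form
#' \deqn{n_C = \frac{n_I (1-\rho)}{1 - n_I\,\rho\,(cv^2+1)/k},}
#' with \eqn{n_I} carried *unrounded* from [rct_sample_size()] — rounding
#' it first inflates `m` for strongly clustered designs. \eqn{n_C} is then
#' rounded up to a multiple of `k` and `m = n_C / k`.
#'
#' The denominator vanishes as the design approaches the feasibility
#' boundary, so `m` diverges there; at or beyond the boundary a
#' `"crctsize_infeasible_error"` is raised carrying the
#' [feasibility_check()] report in its `report` field.
#'
#' @inheritParams feasibility_check
#' @return A one-row tibble of class `"crct_size"` with columns
#'   `n_I_raw`, `n_I`, `vif_at_solution`, `n_C_raw`, `n_C`, `m`, `total`
#'   (both arms combined).
#' @examples
#' # 40% vs 50%, 80% power, 20 clusters per arm, ICC 0.005 -> 22 per cluster
#' required_sample_size_fixed_k(
#'   effect_binary(0.4, 0.5), test_params(0.05, 0.8),
#'   k = 20, rho = 0.005
#' )
#' @export
required_sample_size_fixed_k <- function(effect, test, k, rho, cv = 0) {
  effect <- as_effect_spec(effect)
  test <- as_test_params(test)
  k <- check_count(k, "k")
  check_icc(rho)
  check_positive(cv, "cv", strict = FALSE)

  report <- feasibility_check(effect, test, k, rho, cv)
  size <- rct_sample_size(effect, test)
  if (!report$feasible) {
    abort(
      sprintf(
        paste0(
          "Design infeasible: n_I * rho * (cv^2 + 1) = %.4g is not below k = %d; ",
          "no finite cluster size reaches the target power. ",
          "See `mdd_binary()`/`mdd_continuous()` and `max_achievable_power()`."
        ),
        size$n_raw * rho * (cv^2 + 1), k
      ),
      class = "crctsize_infeasible_error",
      report = report
    )
  }

  n_C_raw <- size$n_raw * (1 - rho) / (1 - size$n_raw * rho * (cv^2 + 1) / k)
  n_C <- ceiling_to_multiple(n_C_raw, k)
  m <- n_C / k

  out <- tibble(
    n_I_raw = size$n_raw,
    n_I = size$n,
    vif_at_solution = vif(m, rho, cv),
    n_C_raw = n_C_raw,
    n_C = as.integer(n_C),
    m = as.integer(m),
    total = as.integer(2 * n_C)
  )
  class(out) <- c("crct_size", class(out))
  out
}

#' Required number of clusters for a fixed cluster size
#'
#' The conventional direction: with (average) cluster size `m` known, the
#' number of clusters per arm is the inflated individually-randomised size
#' rounded up to whole clusters,
#' \deqn{k = \lceil n_I\,VIF / m \rceil,}
#' again with \eqn{n_I} unrounded.
#'
#' @param m Individuals per cluster (average when `cv > 0`).
#' @inheritParams feasibility_check
#' @return Number of clusters per arm (integer).
#' @examples
#' required_clusters_fixed_m(effect_binary(0.4, 0.5), test_params(), m = 22, rho = 0.005)
#' @export
required_clusters_fixed_m <- function(effect, test, m, rho, cv = 0) {
  effect <- as_effect_spec(effect)
  test <- as_test_params(test)
  size <- rct_sample_size(effect, test)
  as.integer(ceiling(size$n_raw * vif(m, rho, cv) / m))
}
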