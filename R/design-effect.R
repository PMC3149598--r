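#' Variance inflation factor (design effect) for cluster randomisation
#'
#' For equal cluster sizes (`cv = 0`) the classic design effect
#' \deqn{VIF = 1 + (m-1)\rho,}
#' and for unequal sizes with coefficient of variation `cv` the
#' approximation
#' \deqn{VIF = 1 + ((cv^2+1)\bar m - 1)\rho,}
#' where `m` is then the average cluster size \eqn{\bar m}. `cv = 0`
#' recovers the equal-size expression exactly.
#'
#' @param m Cluster size (average size when `cv > 0`); >= 1, need not be
#'   an integer.
#' @param rho Intra-cluster correlation \eqn{\rho \in [0, 1)}. Negative
#'   ICCs are rejected: the framework assumes clustering inflates variance.
#' @param cv Coefficient of variation of cluster sizes (SD/mean), >= 0.
#' @return The inflation factor, >= 1.
#' @examples
#' vif(22, 0.005)            # 1.105
#' vif(50, 0.01, cv = 0.65)  # 1.70125
#' @export
vif <- function(m, rho, cv = 0) {
  check_positive(m, "m")
  if (m < 1) stop_domain("`m` must be >= 1.")
  check_icc(rho)
  check_positive(cv, "cv", strict = FALSE)
  1 + ((cv^2 + 1) * m - 1) * rho
}

#' Variance of the estimated difference in a cluster randomised trial
#'
#' With `k` clusters per arm of (average) size `m`,
#' \deqn{\mathrm{var}(d_C) = \frac{2\sigma^2 \, VIF}{k m}.}
#' Strictly decreasing in `m`, but bounded below by
#' [precision_bound_variance()] whenever \eqn{\rho > 0}.
#'
#' @param sigma_sq Outcome variance.
#' @param k Clusters per arm.
#' @param m Individuals per cluster (average when `cv > 0`).
#' @inheritParams vif
#' @return The variance of the difference estimate.
#' @examples
#' difference_variance(0.245, k = 20, m = 22, rho = 0.005)
#' @export
difference_variance <- function(sigma_sq, k, m, rho, cv = 0) {
  check_positive(sigma_sq, "sigma_sq")
  check_count(k, "k")
  2 * sigma_sq * vif(m, rho, cv) / (k * m)
}

#' Precision bound: the variance floor as cluster sizes grow
#'
#' As \eqn{m \to \infty} the variance of the difference estimate does not
#' vanish but tends to
#' \deqn{\frac{2\sigma^2 \rho (cv^2+1)}{k},}
#' the one-line limit of `2 sigma_sq * (1 + ((cv^2+1)m - 1)rho) / (k m)`.
#' This floor is what makes some fixed-`k` designs infeasible and is the
#' quantity behind the minimum detectable difference and maximum
#' achievable power.
#'
#' @inheritParams difference_variance
#' @return The limiting variance (0 when `rho = 0`).
#' @examples
#' precision_bound_variance(0.245, k = 20, rho = 0.07)
#' @export
precision_bound_variance <- function(sigma_sq, k, rho, cv = 0) {
  check_positive(sigma_sq, "sigma_sq")
  check_count(k, "k")
  check_icc(rho)
  check_positive(cv, "cv", strict = FALSE)
  2 * sigma_sq * rho * (cv^2 + 1) / k
}

#' Coefficient of variation of a vector of cluster sizes
#'
#' Convenience for feeding observed (unequal) cluster sizes into the
#' `cv`-based approximation: returns `sd(sizes) / mean(sizes)` using the
#' usual (denominator n-1) sample standard deviation.
#'
#' @param sizes Positive cluster sizes (length >= 1).
#' @return A list with `cv`, `mean` and `n_clusters`.
#' @examples
#' cluster_size_cv(c(30, 50, 70))
#' @export
cluster_size_cv <- function(sizes) {
  if (!is.numeric(sizes) || length(sizes) < 1L || anyNA(sizes) || any(sizes <= 0)) {
    stop_domain("`sizes` must be positive numbers.")
  }
  m_bar <- mean(sizes)
  list(
    cv = if (length(sizes) == 1L) 0 else sd(sizes) / m_bar,
    mean = m_bar,
    n_clusters = length(sizes)
  )
}
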