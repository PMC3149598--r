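# Published-example reproduction and the parameter grids behind the
# limiting-power / minimum-detectable-difference figures.

#' Recompute the published worked-example table
#'
#' The worked example: a trial to detect an increase in an event rate from
#' 40%, with 20 clusters per arm, at 80% and 90% power, under a low
#' (0.005) and a high (0.07) ICC. At the low ICC the 40% vs 50% design is
#' feasible and the table gives \eqn{n_I}, \eqn{n_C} and `m`; at the high
#' ICC it is infeasible, and the table gives the minimum detectable
#' difference (rounded up at two decimals) and the design sized at that
#' rounded difference (40% vs 52% and 40% vs 54%).
#'
#' Every cell is recomputed from scratch and compared with the published
#' value. Reproducing all of them requires two conventions this package
#' uses throughout: the unrounded \eqn{n_I} is carried into the
#' fixed-cluster formula, and MDDs are rounded up, never to nearest.
#'
#' @param alpha Two-sided significance level. Default 0.05.
#' @return A tibble with one row per table cell: `icc`, `power`,
#'   `quantity`, `computed`, `printed` and `match`.
#' @examples
#' reproduce_table1()
#' @export
reproduce_table1 <- function(alpha = 0.05) {
  check_probability(alpha, "alpha")
  pi1 <- 0.4
  k <- 20

  printed <- tibble::tribble(
    ~icc,  ~power, ~quantity, ~printed,
    0.005, 0.8,    "n_I",     385,
    0.005, 0.8,    "n_C",     440,
    0.005, 0.8,    "m",       22,
    0.005, 0.9,    "n_I",     515,
    0.005, 0.9,    "n_C",     600,
    0.005, 0.9,    "m",       30,
    0.07,  0.8,    "mdd",     0.12,
    0.07,  0.8,    "n_I",     267,
    0.07,  0.8,    "n_C",     3780,
    0.07,  0.8,    "m",       189,
    0.07,  0.9,    "mdd",     0.14,
    0.07,  0.9,    "n_I",     262,
    0.07,  0.9,    "n_C",     2920,
    0.07,  0.9,    "m",       146
  )

  cell_value <- function(icc, power, quantity) {
    test <- test_params(alpha, power)
    if (icc == 0.005) {
      design <- required_sample_size_fixed_k(
        effect_binary(pi1, 0.5), test, k = k, rho = icc
      )
      switch(quantity,
        n_I = design$n_I, n_C = design$n_C, m = design$m
      )
    } else {
      mdd <- mdd_binary(pi1, test, k = k, rho = icc)
      if (quantity == "mdd") return(mdd$d_mdd_rounded)
      design <- required_sample_size_fixed_k(
        effect_binary(pi1, pi1 + mdd$d_mdd_rounded), test, k = k, rho = icc
      )
      switch(quantity,
        n_I = design$n_I, n_C = design$n_C, m = design$m
      )
    }
  }

  out <- printed |>
    dplyr::mutate(
      computed = purrr::pmap_dbl(
        list(.data$icc, .data$power, .data$quantity), cell_value
      ),
      match = .data$computed == .data$printed
    ) |>
    dplyr::select("icc", "power", "quantity", "computed", "printed", "match")
  class(out) <- c("crct_table1", class(out))
  out
}

#' Grids of limiting power and detectable difference
#'
#' Evaluates one of the four limiting quantities over a grid of clusters
#' per arm, ICCs and effects — the grids behind the standard "limiting
#' values as the cluster size approaches infinity" figures:
#'
#' * `"map_continuous"`: maximum achievable power for standardised effect
#'   sizes (`effect_values`, default 0.05–0.30);
#' * `"map_binary"`: maximum achievable power to detect a +0.1 increase
#'   over baseline proportions (`effect_values`, default 0.05–0.5);
#' * `"mdd_continuous"`: minimum detectable standardised effect size
#'   (`effect_values` ignored);
#' * `"mdd_binary"`: minimum detectable increase over baseline
#'   proportions.
#'
#' @param quantity One of the four names above.
#' @param test A [test_params()] object (its power is not used for the
#'   MAP quantities beyond defaults; default 0.05 / 0.8).
#' @param k_values Clusters per arm to tabulate. Default
#'   `c(10, 20, 30, 50, 100)`.
#' @param rho_values ICC grid. Default `seq(0, 0.1, by = 0.005)`.
#' @param effect_values Standardised effect sizes or baseline proportions,
#'   by quantity (see above).
#' @param binary_increase Increase added to each baseline proportion for
#'   `"map_binary"`. Default 0.1.
#' @return A tibble of class `"crct_grid"`: `quantity`, `k`, `rho`,
#'   `effect` (`NA` for `"mdd_continuous"`) and `value`. Deterministic.
#' @examples
#' compute_grid("mdd_continuous", k_values = 10, rho_values = 0.02)
#' @export
compute_grid <- function(quantity = c("map_continuous", "map_binary",
                                      "mdd_continuous", "mdd_binary"),
                         test = test_params(0.05, 0.8),
                         k_values = c(10L, 20L, 30L, 50L, 100L),
                         rho_values = seq(0, 0.1, by = 0.005),
                         effect_values = NULL,
                         binary_increase = 0.1) {
  quantity <- match.arg(quantity)
  test <- as_test_params(test)
  if (length(k_values) < 1 || length(rho_values) < 1) {
    stop_domain("`k_values` and `rho_values` must be non-empty.")
  }
  if (is.null(effect_values)) {
    effect_values <- switch(quantity,
      map_continuous = seq(0.05, 0.30, by = 0.05),
      map_binary = seq(0.05, 0.5, by = 0.05),
      mdd_continuous = NA_real_,
      mdd_binary = seq(0.05, 0.5, by = 0.05)
    )
  }

  grid <- tidyr::expand_grid(
    quantity = quantity, k = as.integer(k_values),
    rho = rho_values, effect = effect_values
  )
  value_of <- function(k, rho, effect) {
    switch(quantity,
      map_continuous = max_achievable_power(
        effect_continuous(effect), test$alpha, k = k, rho = rho
      ),
      map_binary = max_achievable_power(
        effect_binary(effect, effect + binary_increase), test$alpha,
        k = k, rho = rho
      ),
      mdd_continuous = mdd_continuous(1, test, k = k, rho = rho),
      mdd_binary = mdd_binary(effect, test, k = k, rho = rho)$d_mdd
    )
  }
  out <- grid |>
    dplyr::mutate(value = purrr::pmap_dbl(
      list(.data$k, .data$rho, .data$effect), value_of
    ))
  class(out) <- c("crct_grid", class(out))
  out
}

#' Plot a limiting-quantity grid
#'
#' @param object A `"crct_grid"` tibble from [compute_grid()].
#' @param ... Unused.
#' @return A ggplot: the limiting quantity against the ICC, one line per
#'   number of clusters, faceted by effect where the grid varies it.
#' @exportS3Method ggplot2::autoplot
autoplot.crct_grid <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$rho, y = .data$value,
                                            colour = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Intra-cluster correlation (ICC)",
      y = unique(object$quantity),
      colour = "Clusters per arm"
    )
  if (length(unique(object$effect[!is.na(object$effect)])) > 1) {
    p <- p + ggplot2::facet_wrap(~effect)
  }
  p
}
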