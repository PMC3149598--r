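#' Design advice for a cluster trial with a fixed number of clusters
#'
#' Runs the full planning workflow for a two-arm cluster randomised trial
#' with `k` clusters available per arm:
#'
#' 1. the individually-randomised baseline size \eqn{n_I};
#' 2. the feasibility check \eqn{k > n_I\rho(cv^2+1)} at the stated `cv`;
#' 3. if infeasible and clusters are unequal, a re-check at `cv = 0`
#'    ("would equalising cluster sizes rescue the design?");
#' 4. if still infeasible, the design limits — minimum detectable
#'    difference and maximum achievable power — plus concrete remediation
#'    suggestions (each self-checked to yield a feasible design);
#' 5. if feasible, the required cluster size via
#'    [required_sample_size_fixed_k()].
#'
#' A warning is attached when `k < 5`: trials with fewer than five
#' clusters per arm are widely considered inadvisable (MRC guidance), both
#' for bias and because the normal approximations used here degrade.
#'
#' @param effect An [effect_continuous()] or [effect_binary()] object.
#' @param test A [test_params()] object.
#' @param k Clusters per arm.
#' @param rho Intra-cluster correlation in [0, 1).
#' @param cv Coefficient of variation of cluster sizes, >= 0.
#' @param power_margin Subtracted from the maximum achievable power when
#'   suggesting a reduced target power. The default 0 reports the MAP
#'   itself, flagged as a supremum that finite cluster sizes approach but
#'   never attain.
#' @param difference_granularity Step used when suggesting an enlarged
#'   target difference: the suggestion is the smallest multiple of this
#'   step strictly beyond the minimum detectable difference. Default 0.01
#'   (one percentage point for binary outcomes).
#'
#' @return An object of class `"crct_advice"`: a list with elements
#'   `effect`, `test`, `k`, `rho`, `cv`, `n_I_raw`, `n_I`, `feasibility`
#'   (a [feasibility_check()] tibble), exactly one of `feasible_design`
#'   (a [required_sample_size_fixed_k()] tibble) or `limits` (a one-row
#'   tibble with `bound_variance`, MDD fields and `map`), `suggestions`
#'   (a tibble, possibly empty) and `warnings` (character).
#' @examples
#' advise(effect_binary(0.4, 0.5), test_params(0.05, 0.8), k = 20, rho = 0.005)
#' advise(effect_binary(0.4, 0.5), test_params(0.05, 0.8), k = 20, rho = 0.07)
#' @export
advise <- function(effect, test, k, rho, cv = 0,
                   power_margin = 0, difference_granularity = 0.01) {
  effect <- as_effect_spec(effect)
  test <- as_test_params(test)
  k <- check_count(k, "k")
  check_icc(rho)
  check_positive(cv, "cv", strict = FALSE)
  check_positive(power_margin, "power_margin", strict = FALSE)
  check_positive(difference_granularity, "difference_granularity")

  size <- rct_sample_size(effect, test)
  feas <- feasibility_check(effect, test, k, rho, cv)

  warnings <- character()
  if (k < 5) {
    warnings <- c(
      warnings,
      sprintf(
        "Only %d clusters per arm: trials with fewer than 5 clusters per arm are inadvisable (MRC guidance); normal approximations are also unreliable at this size.",
        k
      )
    )
  }

  feasible_design <- NULL
  limits <- NULL
  suggestions <- empty_suggestions()

  if (feas$feasible) {
    feasible_design <- required_sample_size_fixed_k(effect, test, k, rho, cv)
  } else {
    limits <- design_limits(effect, test, k, rho, cv)
    suggestions <- dplyr::bind_rows(
      suggest_equal_clusters(effect, test, k, rho, cv),
      suggest_reduced_power(effect, test, k, rho, cv, limits$map, power_margin),
      suggest_larger_difference(effect, test, k, rho, cv, limits,
                                difference_granularity)
    )
    if (nrow(suggestions) > 0 && !all(suggestions$verified)) {
      warnings <- c(
        warnings,
        "Internal self-check failed for at least one suggestion; inspect `suggestions$verified`."
      )
    }
  }

  structure(
    list(
      effect = effect, test = test, k = k, rho = rho, cv = cv,
      n_I_raw = size$n_raw, n_I = size$n,
      feasibility = feas,
      feasible_design = feasible_design,
      limits = limits,
      suggestions = suggestions,
      warnings = warnings
    ),
    class = "crct_advice"
  )
}

# Limits block for an infeasible design: precision floor, MDD and MAP.
design_limits <- function(effect, test, k, rho, cv) {
  bound <- precision_bound_variance(effect$sigma_sq, k, rho, cv)
  map <- max_achievable_power(effect, test$alpha, k, rho, cv)
  if (effect$kind == "binary") {
    mdd <- mdd_binary(effect$pi1, test, k, rho, cv)
    out <- tibble(
      bound_variance = bound,
      d_mdd = mdd$d_mdd,
      d_mdd_rounded = mdd$d_mdd_rounded,
      pi2_lower = mdd$pi2_lower,
      pi2_upper = mdd$pi2_upper,
      map = map
    )
  } else {
    d_mdd <- mdd_continuous(effect$sigma_sq, test, k, rho, cv)
    out <- tibble(
      bound_variance = bound,
      d_mdd = d_mdd,
      d_mdd_rounded = ceiling_2dp(d_mdd),
      pi2_lower = NA_real_,
      pi2_upper = NA_real_,
      map = map
    )
  }
  class(out) <- c("crct_limits", class(out))
  out
}

empty_suggestions <- function() {
  tibble(
    action = character(), value = numeric(),
    detail = character(), verified = logical()
  )
}

suggest_equal_clusters <- function(effect, test, k, rho, cv) {
  if (cv == 0) return(empty_suggestions())
  feas_equal <- feasibility_check(effect, test, k, rho, cv = 0)
  if (!feas_equal$feasible) return(empty_suggestions())
  design <- required_sample_size_fixed_k(effect, test, k, rho, cv = 0)
  tibble(
    action = "equalise_cluster_sizes",
    value = 0,
    detail = sprintf(
      "With equal cluster sizes (cv = 0) the design is feasible: m = %d per cluster.",
      design$m
    ),
    verified = TRUE
  )
}

suggest_reduced_power <- function(effect, test, k, rho, cv, map, power_margin) {
  value <- map - power_margin
  if (value <= 0 || value >= 1) return(empty_suggestions())
  # The MAP itself is a supremum: check feasibility just inside it when no
  # margin is requested.
  check_at <- if (power_margin == 0) value - 1e-9 else value
  verified <- feasibility_check(
    effect, test_params(test$alpha, check_at), k, rho, cv
  )$feasible
  tibble(
    action = "reduce_power",
    value = value,
    detail = if (power_margin == 0) {
      sprintf(
        "Maximum achievable power is %.4f - a supremum approached, never attained, as clusters grow; plan for strictly less.",
        map
      )
    } else {
      sprintf(
        "Reduce target power to %.4f (maximum achievable %.4f minus margin %.3f).",
        value, map, power_margin
      )
    },
    verified = verified
  )
}

suggest_larger_difference <- function(effect, test, k, rho, cv, limits,
                                      granularity) {
  if (effect$kind == "binary") {
    increase <- effect$d > 0
    # Step outward from the relevant root to the next point on the grid.
    if (increase) {
      pi2_new <- granularity * ceiling(limits$pi2_upper / granularity)
      if (pi2_new <= limits$pi2_upper) pi2_new <- pi2_new + granularity
    } else {
      pi2_new <- granularity * floor(limits$pi2_lower / granularity)
      if (pi2_new >= limits$pi2_lower) pi2_new <- pi2_new - granularity
    }
    if (pi2_new <= 0 || pi2_new >= 1) return(empty_suggestions())
    new_effect <- effect_binary(effect$pi1, pi2_new)
    verified <- feasibility_check(effect = new_effect, test = test,
                                  k = k, rho = rho, cv = cv)$feasible
    design <- if (verified) {
      required_sample_size_fixed_k(new_effect, test, k, rho, cv)
    }
    tibble(
      action = "increase_difference",
      value = pi2_new,
      detail = sprintf(
        "Smallest detectable intervention proportion on a %.2f grid: pi2 = %.2f (difference %.2f)%s.",
        granularity, pi2_new, abs(pi2_new - effect$pi1),
        if (verified) sprintf("; requires m = %d per cluster", design$m) else ""
      ),
      verified = verified
    )
  } else {
    d_new <- granularity * ceiling(limits$d_mdd / granularity)
    if (d_new <= limits$d_mdd) d_new <- d_new + granularity
    new_effect <- effect_continuous(sign(effect$d) * d_new,
                                    sigma_sq = effect$sigma_sq)
    verified <- feasibility_check(effect = new_effect, test = test,
                                  k = k, rho = rho, cv = cv)$feasible
    design <- if (verified) {
      required_sample_size_fixed_k(new_effect, test, k, rho, cv)
    }
    tibble(
      action = "increase_difference",
      value = sign(effect$d) * d_new,
      detail = sprintf(
        "Smallest detectable difference on a %.2f grid: |d| = %.2f%s.",
        granularity, d_new,
        if (verified) sprintf("; requires m = %d per cluster", design$m) else ""
      ),
      verified = verified
    )
  }
}

#' @export
print.crct_advice <- function(x, ...) {
  cat("Cluster-randomised trial design advice\n")
  cat("--------------------------------------\n")
  print(x$effect)
  print(x$test)
  cat(sprintf(
    "Clusters per arm k = %d, ICC rho = %g, cluster-size cv = %g\n",
    x$k, x$rho, x$cv
  ))
  cat(sprintf(
    "Individual randomisation: n_I = %d per arm (unrounded %.3f)\n",
    x$n_I, x$n_I_raw
  ))
  f <- x$feasibility
  cat(sprintf(
    "Feasibility: n_I * rho * (cv^2+1) = %.4g %s k = %d -> %s\n",
    f$product, if (f$feasible) "<" else ">=", f$k,
    if (f$feasible) "FEASIBLE" else "INFEASIBLE"
  ))
  if (!is.null(x$feasible_design)) {
    d <- x$feasible_design
    cat(sprintf(
      "Required: m = %d per cluster, n_C = %d per arm, %d in total.\n",
      d$m, d$n_C, d$total
    ))
  } else {
    l <- x$limits
    cat(sprintf(
      "Limits as clusters grow: MDD = %.4f (%.2f rounded up), MAP = %.4f\n",
      l$d_mdd, l$d_mdd_rounded, l$map
    ))
    if (nrow(x$suggestions) > 0) {
      cat("Suggestions:\n")
      for (i in seq_len(nrow(x$suggestions))) {
        cat(sprintf("  - %s\n", x$suggestions$detail[i]))
      }
    }
  }
  for (w in x$warnings) cat(sprintf("Warning: %s\n", w))
  invisible(x)
}

#' Tidy the suggestions of a design-advice report
#'
#' @param x A `"crct_advice"` object from [advise()].
#' @param ... Unused.
#' @return The suggestions tibble (zero rows for a feasible design),
#'   with the `action`, `value`, `detail` and `verified` columns.
#' @exportS3Method generics::tidy
tidy.crct_advice <- function(x, ...) {
  x$suggestions
}

#' One-row summary of a design-advice report
#'
#' @param x A `"crct_advice"` object from [advise()].
#' @param ... Unused.
#' @return A one-row tibble: design parameters, `n_I`, `feasible`, and
#'   either the required `m`/`n_C` or the MDD/MAP limits (`NA` on the
#'   side that does not apply).
#' @exportS3Method generics::glance
glance.crct_advice <- function(x, ...) {
  tibble(
    kind = x$effect$kind,
    d = x$effect$d,
    alpha = x$test$alpha,
    power = x$test$power,
    k = x$k,
    rho = x$rho,
    cv = x$cv,
    n_I = x$n_I,
    feasible = x$feasibility$feasible,
    m = if (!is.null(x$feasible_design)) x$feasible_design$m else NA_integer_,
    n_C = if (!is.null(x$feasible_design)) x$feasible_design$n_C else NA_integer_,
    d_mdd = if (!is.null(x$limits)) x$limits$d_mdd else NA_real_,
    map = if (!is.null(x$limits)) x$limits$map else NA_real_,
    n_warnings = length(x$warnings)
  )
}

#' Serialise a design-advice report to JSON
#'
#' Machine-readable counterpart of the printed report, used by the
#' command-line interface's `--json` mode.
#'
#' @param x A `"crct_advice"` object.
#' @param pretty Pretty-print the JSON. Default `TRUE`.
#' @return A JSON string (class `"json"`).
#' @export
advice_json <- function(x, pretty = TRUE) {
  if (!inherits(x, "crct_advice")) stop_domain("`x` must be a `crct_advice` object.")
  payload <- list(
    effect = unclass(x$effect),
    test = unclass(x$test)[c("alpha", "power")],
    k = x$k, rho = x$rho, cv = x$cv,
    n_I = x$n_I, n_I_raw = x$n_I_raw,
    feasibility = as.list(x$feasibility),
    feasible_design = if (!is.null(x$feasible_design)) as.list(x$feasible_design),
    limits = if (!is.null(x$limits)) as.list(x$limits),
    suggestions = x$suggestions,
    warnings = x$warnings
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = pretty,
                   null = "null")
}
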