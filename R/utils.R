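# Input validation and rounding helpers shared across the calculators.
# All domain violations raise a condition of class "crctsize_domain_error"
# so callers (and the CLI) can distinguish bad input from infeasibility.

stop_domain <- function(msg, ...) {
  abort(msg, class = "crctsize_domain_error", ...)
}

check_probability <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_domain(sprintf("`%s` must be a single number.", name))
  }
  if (open && (x <= 0 || x >= 1)) {
    stop_domain(sprintf("`%s` must lie strictly between 0 and 1 (got %g).", name, x))
  }
  if (!open && (x < 0 || x > 1)) {
    stop_domain(sprintf("`%s` must lie in [0, 1] (got %g).", name, x))
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_domain(sprintf("`%s` must be a single number.", name))
  }
  if (strict && x <= 0) stop_domain(sprintf("`%s` must be > 0 (got %g).", name, x))
  if (!strict && x < 0) stop_domain(sprintf("`%s` must be >= 0 (got %g).", name, x))
  invisible(x)
}

check_icc <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0 || rho >= 1) {
    stop_domain(sprintf(
      "`rho` (intra-cluster correlation) must lie in [0, 1); got %s.",
      format(rho)
    ))
  }
  invisible(rho)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_domain(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Round n up to the next multiple of k (exact multiples are unchanged).
ceiling_to_multiple <- function(n, k) {
  k * ceiling(n / k)
}

# Conservative two-decimal rounding: always up, never down.  Used for
# reporting minimum detectable differences (a difference rounded down
# would be claimed detectable when it is not).
ceiling_2dp <- function(x) {
  ceiling(x * 100) / 100
}
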