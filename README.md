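# crctsize

Design calculations for two-arm cluster randomised controlled trials
(CRCTs) in which the **number of clusters per arm is fixed** — the common
situation in health-services research, where a known set of practices,
schools or wards has agreed to take part and the open question is how many
individuals to recruit per cluster.

## The statistics

Clustering inflates the variance of the estimated difference between arms
by the design effect (variance inflation factor)
`VIF = 1 + (m − 1)ρ` for `k` clusters per arm of size `m` and intra-cluster
correlation `ρ` (or `1 + ((cv² + 1)m̄ − 1)ρ` for unequal sizes with
coefficient of variation `cv`). Because

```
var(d_C) = 2σ²·VIF / (k·m)  →  2σ²ρ(cv² + 1)/k   as m → ∞,
```

precision has a floor when `k` is fixed. The package implements the
consequences:

* **Feasibility check**: the target difference is reachable at the target
  power iff `k > n_I·ρ·(cv² + 1)`, where `n_I` is the per-arm size under
  individual randomisation.
* **Required cluster size** for feasible designs:
  `n_C = n_I(1 − ρ) / (1 − n_I·ρ·(cv² + 1)/k)`, rounded up to a multiple
  of `k`, with `m = n_C/k` (`n_I` carried unrounded — the convention that
  reproduces the published per-cluster sizes).
* **Minimum detectable difference (MDD)** and **maximum achievable power
  (MAP)** for infeasible designs — the limits imposed by the precision
  floor as cluster sizes grow without bound, for continuous outcomes and
  for proportions (where the MDD solves a quadratic in `π₂` because the
  pooled variance depends on the solution).
* **An advisor** (`advise()`) that runs the whole workflow and suggests
  verified remediations: equalise cluster sizes, lower the power target
  below the MAP, or enlarge the target difference beyond the MDD.
* **A Monte-Carlo validator** (`empirical_power()`) that simulates
  cluster-correlated trials (normal cluster-effects model or beta-binomial
  counts) and checks the analytic power formulas against the rejection
  rate of the cluster-mean z-test.

Binary outcomes use the pooled normal-approximation variance
`σ² = (π₁(1−π₁) + π₂(1−π₂))/2` throughout.

## Worked example

Twenty clusters per arm are available to detect an increase in an event
rate from 40% to 50% (two-sided α = 0.05, 80% power). Whether that design
is possible depends entirely on the ICC:

```r
library(crctsize)

advise(effect_binary(0.4, 0.5), test_params(0.05, 0.8), k = 20, rho = 0.005)
#> Cluster-randomised trial design advice
#> --------------------------------------
#> Binary effect: pi1 = 0.4, pi2 = 0.5 (d = 0.1, pooled sigma^2 = 0.245)
#> Two-sided test: alpha = 0.05 (z = 1.959964), power = 0.8 (z = 0.841621)
#> Clusters per arm k = 20, ICC rho = 0.005, cluster-size cv = 0
#> Individual randomisation: n_I = 385 per arm (unrounded 384.595)
#> Feasibility: n_I * rho * (cv^2+1) = 1.925 < k = 20 -> FEASIBLE
#> Required: m = 22 per cluster, n_C = 440 per arm, 880 in total.
```

At ρ = 0.005 the answer is 22 individuals per cluster. At ρ = 0.07 the same
trial is impossible at any cluster size — `385 × 0.07 = 26.95 > 20` — and
the report turns to what *is* achievable:

```r
advise(effect_binary(0.4, 0.5), test_params(0.05, 0.8), k = 20, rho = 0.07)
#> ...
#> Feasibility: n_I * rho * (cv^2+1) = 26.95 >= k = 20 -> INFEASIBLE
#> Limits as clusters grow: MDD = 0.1160 (0.12 rounded up), MAP = 0.6754
#> Suggestions:
#>   - Maximum achievable power is 0.6754 - a supremum approached, never
#>     attained, as clusters grow; plan for strictly less.
#>   - Smallest detectable intervention proportion on a 0.01 grid:
#>     pi2 = 0.52 (difference 0.12); requires m = 189 per cluster.
```

The smallest detectable increase is 12 percentage points (0.1160 before
conservative rounding), power can never exceed 0.675 for the original 10-point
difference, and detecting 40% → 52% instead needs 189 individuals in each of
the 20 clusters. `glance()` and `tidy()` return the same report as tibbles;
`reproduce_table1()` recomputes every cell of the published example table;
`compute_grid()` + `autoplot()` tabulate and plot MDD/MAP over (k, ρ, effect)
grids.

The Monte-Carlo validator confirms the analytic power at the feasible
design (analytic 0.8135 for d = 0.1, σ² = 0.245 at k = 20, m = 22,
ρ = 0.005):

```r
empirical_power(sim_config(k = 20, m = 22, rho = 0.005,
                           effect = effect_continuous(0.1, sigma_sq = 0.245),
                           n_sims = 2000, seed = 1))
#>   empirical_power       mc_se analytic_power z_discrepancy
#> 1           0.809 0.008789738      0.8134569    -0.5070598
```

## Command line

A thin script wraps the same functions:

```sh
Rscript inst/cli/crct.R cluster-size --pi1 0.4 --pi2 0.5 --k 20 --icc 0.005
Rscript inst/cli/crct.R advise --pi1 0.4 --pi2 0.5 --k 20 --icc 0.07 --json
Rscript inst/cli/crct.R grid --quantity mdd_binary --out grid.csv
```

Subcommands: `feasibility`, `cluster-size`, `power`, `detectable-diff`,
`mdd`, `map`, `advise`, `table1`, `grid`, `validate`. A `--config FILE` of
`key=value` lines supplies defaults; explicit flags override it. Exit codes:
0 success, 2 usage/domain error, 3 when `cluster-size` is asked for an
infeasible design.

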