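---
title: "Designing cluster randomised trials with a fixed number of clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing cluster randomised trials with a fixed number of clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crctsize)
```

## The problem

In a cluster randomised controlled trial (CRCT) intact groups — general
practices, schools, wards — are randomised to arms, and outcomes on
individuals within a cluster are correlated. Standard CRCT sample-size
formulas treat the cluster size $m$ as known and solve for the number of
clusters $k$. In health-services research the constraint usually runs the
other way: a fixed set of $k$ clusters per arm has agreed to take part, and
the designer must choose how many individuals to recruit per cluster.

That inversion is not symmetric. Adding clusters buys precision without
limit; enlarging clusters does not. With the intra-cluster correlation
coefficient (ICC) $\rho$ and outcome variance $\sigma^2$, the variance of
the estimated difference between arms is

$$\mathrm{var}(d_C) \;=\; \frac{2\sigma^2\,\mathrm{VIF}}{km},
\qquad \mathrm{VIF} = 1 + (m-1)\rho,$$

which as $m \to \infty$ tends not to zero but to the *precision floor*

$$\frac{2\sigma^2\rho\,(cv^2+1)}{k},$$

where $cv$ is the coefficient of variation of cluster sizes ($cv = 0$ for
equal clusters; the unequal-size variance inflation factor is
$1 + ((cv^2+1)\bar m - 1)\rho$). Some designs are therefore *infeasible*:
no cluster size, however large, reaches the target power. This package
computes the required cluster size when the design is feasible, detects
when it is not, and quantifies what is still achievable when it is not.

## The calculations

All formulas are two-sided normal approximations. With
$z_{\alpha/2} = \Phi^{-1}(1-\alpha/2)$ and $z_\beta = \Phi^{-1}(1-\beta)$:

* **Individual randomisation baseline** (`rct_sample_size()`):
  $n_I = (z_{\alpha/2}+z_\beta)^2\,2\sigma^2/d^2$ per arm. For binary
  outcomes $d = \pi_2-\pi_1$ and $\sigma^2$ is the pooled approximation
  $(\pi_1(1-\pi_1)+\pi_2(1-\pi_2))/2$.
* **Feasibility** (`feasibility_check()`): the design can reach the target
  power iff $k > n_I\,\rho\,(cv^2+1)$, strictly. Equality corresponds to
  infinitely large clusters and is classified infeasible.
* **Required cluster size** (`required_sample_size_fixed_k()`): substituting
  $m = n_C/k$ into the inflated sample size and solving gives
  $$n_C = \frac{n_I(1-\rho)}{1 - n_I\,\rho\,(cv^2+1)/k},$$
  rounded up to a multiple of $k$; $m = n_C/k$.
* **Limits for infeasible designs** (`mdd_continuous()`, `mdd_binary()`,
  `max_achievable_power()`): the minimum detectable difference (MDD)
  $d_{MDD} = (z_{\alpha/2}+z_\beta)\sqrt{2\sigma^2\rho(cv^2+1)/k}$ and the
  maximum achievable power (MAP)
  $\Phi\!\big(|d|/\sqrt{2\sigma^2\rho(cv^2+1)/k} - z_{\alpha/2}\big)$. For
  binary outcomes the MDD keeps the pooled variance evaluated *at the
  solution*: $\pi_2$ solves
  $(\pi_2-\pi_1)^2 = w\,(\pi_1(1-\pi_1)+\pi_2(1-\pi_2))$ with
  $w = \rho(cv^2+1)(z_{\alpha/2}+z_\beta)^2/k$, a quadratic
  $a\pi_2^2+b\pi_2+c=0$ with $a = -(1+w)$, $b = 2\pi_1+w$ and
  $c = w\pi_1-\pi_1^2(1+w)$, whose two roots bracket $\pi_1$ (the upper
  root limits an increase, the lower a decrease). The constant coefficient
  $c$ is derived directly from the defining relation above and is validated
  in the test suite by the residual of that relation at both roots
  ($<10^{-10}$) and by an independent `polyroot()` cross-check.

MDD and MAP are exact duals: evaluating the MAP at the MDD for target power
$p$ returns $p$. The test suite asserts this to $10^{-10}$ (continuous) and
$10^{-8}$ (binary, where the variance is recomputed at the root).

## Numerical conventions

Three conventions matter for reproducing published tables, and the package
applies them everywhere:

1. **Full-precision quantiles.** $z_{0.975} = 1.959964\ldots$ and
   $z_{0.8} = 0.841621\ldots$, never the two-decimal 1.96/0.84. Truncated
   quantiles shift borderline integer results (for example the 40% vs 50%,
   90%-power baseline moves off 515).
2. **The unrounded $n_I$ enters the fixed-$k$ formula.** Rounding $n_I$ up
   before substituting inflates $m$ when clustering is strong: with the
   integer 267 instead of 266.86 the 40% vs 52% design at $\rho=0.07$,
   $k=20$ yields $m = 190$ rather than the correct 189. The *displayed*
   feasibility product uses the integer $n_I$ (the form in which the check
   is usually quoted, e.g. $385 \times 0.07 = 26.95$), while the feasible /
   infeasible decision uses the unrounded value so that it agrees exactly
   with where the solver diverges; the two can differ only in a vanishing
   band at the boundary, where the unrounded rule is conservative.
3. **Rounding is always up.** $n_C$ is rounded up to a whole multiple of
   $k$ (never to nearest), and reported MDDs are rounded *up* at two
   decimals: rounding 0.1341 to nearest would claim 0.13 detectable when it
   is not. Raw and rounded values are both returned.

Degenerate inputs are handled explicitly: $\rho = 0$ collapses every
cluster formula to its individual-randomisation counterpart (exactly, not
approximately), $cv = 0$ collapses the unequal-size formulas to the
equal-size ones, $d = 0$ gives power $\alpha/2$ (the opposite-tail term of
the power function is omitted, as usual), and the binary MDD at $\rho = 0$
returns the degenerate double root $\pi_2 = \pi_1$ with $d_{MDD}=0$ rather
than solving a vanishing quadratic. ICCs are accepted on $[0,1)$ only;
negative ICCs are rejected because the entire framework models clustering
as variance inflation.

## The advisor

`advise()` packages the workflow a designer actually follows: compute
$n_I$; check feasibility at the stated $cv$; if infeasible and clusters are
unequal, re-check at $cv=0$ (equalising cluster sizes is sometimes enough);
if still infeasible, report the MDD and MAP along with concrete
suggestions; if feasible, size the clusters.

Two advisor choices were genuinely open and are set as follows:

* **Suggested reduced power** defaults to the MAP itself (margin 0),
  explicitly flagged as a supremum that finite cluster sizes approach but
  never attain; a `power_margin` can be subtracted to get an attainable
  target. Reporting the bound rather than prescribing a step below it keeps
  the suggestion assumption-free.
* **Suggested enlarged difference** is the smallest value strictly beyond
  the MDD on a `difference_granularity` grid (default 0.01, i.e. one
  percentage point for proportions — the granularity in which binary
  targets are conventionally quoted). Each suggestion is re-checked for
  feasibility on construction and carries a `verified` flag.

A warning is attached whenever $k < 5$: MRC guidance considers fewer than
five clusters per arm inadvisable, and the normal approximations used here
degrade at such sizes.

## Monte-Carlo validation

The analytic power formula is an approximation twice over: normality of the
difference of cluster means, and a known variance. `sim_config()`,
`simulate_trial()` and `empirical_power()` make those assumptions concrete
and testable:

* **Continuous outcomes** are generated as a shared cluster effect with
  variance $\rho\sigma^2$ plus individual noise with variance
  $(1-\rho)\sigma^2$, so the total variance is $\sigma^2$ and the
  within-cluster correlation is exactly $\rho$; the intervention arm is
  shifted by $d$.
* **Binary outcomes** are beta-binomial: cluster-level event probabilities
  are drawn from a beta distribution with mean $\pi$ and shape sum
  $(1-\rho)/\rho$ (so the ICC on the proportion scale is $\rho$), then
  binomial counts. This matches how $\rho$ combines with the pooled
  proportion variance in the analytic formulas.
* **Analysis** is the two-sample z-test on cluster means, with the variance
  estimated from the dispersion of cluster means — the analysis whose
  variance model the formulas assume. Mixed-model or GEE analyses are out
  of scope.
* **Reproducibility**: one master seed; replicate $r$ derives its own
  substream seed by a fixed congruential mix, so any replicate can be
  regenerated in isolation and results do not depend on execution order.
  The global RNG stream is left untouched.

The test suite validates the generator against an independent one-way
ANOVA ICC estimator (mean estimated ICC within Monte-Carlo error of the
nominal 0.3 over 200 replicates at $k=m=50$), checks null calibration
(rejection rate within Monte-Carlo error of $\alpha$), compares empirical
power with the analytic value at the worked-example design ($k=20$, $m=22$,
$\rho=0.005$, $d=0.1$, $\sigma^2=0.245$; 2,000 replicates), and verifies
that empirical power approaches but never significantly exceeds the MAP as
$m$ grows (up to $m = 2000$ with beta-binomial data). Problem sizes were
chosen so the whole suite validates the formulas at Monte-Carlo standard
errors under 0.01 while remaining quick to run; the null-calibration
scenario uses $k=50$ clusters per arm because the z-test's critical value
is exact only in the large-$k$ limit — at $k=20$ the estimated-variance
z-test rejects a true null slightly more than 5% of the time, a property of
the analysis (a t-style correction is deliberately not applied, to match
the formulas' assumptions), which is why calibration is asserted at a $k$
where the approximation has converged and only observed, not asserted, at
small $k$.

What the simulation does *not* emulate about real trials: unequal cluster
sizes (the analytic $cv$ adjustment is itself an approximation and has no
simulated counterpart here), missing data and dropout, non-normal
continuous outcomes, informative cluster size, and covariate adjustment.
Passing Monte-Carlo checks therefore show that the formulas are internally
consistent with their own assumptions — not that those assumptions hold in
any given field trial.

## Known inconsistencies in the published example

Two numbers sometimes quoted alongside this worked example do not follow
from the formulas above, and this package intentionally does not reproduce
them:

* A 90%-power baseline of **519** per arm for 40% vs 50%. The pooled
  variance gives $n_I = 514.86 \to 515$, which is also the value the
  feasibility arithmetic ($515 \times 0.005 = 2.57$) and the published
  table use; 519 corresponds to an unpooled (Fleiss-style) variance that is
  never part of this framework. The package returns 515.
* A maximum achievable power of **"about 62%"** for $k=15$, $\rho=0.05$,
  40% vs 50%. The closed form with the pooled variance gives 0.6965, and no
  variance convention consistent with the rest of the framework yields
  0.62. The package returns 0.6965.

## Limitations

Equal allocation and equal variances across arms are assumed throughout;
there is no continuity correction for binary outcomes, no one-sided mode,
and no exact (binomial or t) test. The $cv$ adjustment approximates unequal
cluster sizes through their first two moments only. For very small numbers
of clusters the normal approximations — and therefore every number this
package produces — should be treated as optimistic.
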