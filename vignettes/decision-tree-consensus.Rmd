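---
title: "Consensus building for key comparisons: models, tests, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus building for key comparisons: models, tests, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcdtree)
```

## The problem

A key comparison asks several national metrology institutes to measure the
same measurand. Each laboratory `j` reports a value `x_j`, a standard
uncertainty `u_j`, and sometimes the degrees of freedom `nu_j` supporting
that uncertainty. The organisers must then produce a key comparison
reference value (KCRV) with its uncertainty, and for every laboratory a
degree of equivalence `D_j = x_j - KCRV` with an expanded uncertainty
`U95(D_j)` that says whether the lab's result is unusual.

Real comparisons are messy in two recurring ways. First, the measured
values are often more dispersed than the reported uncertainties can
explain — *dark uncertainty*, modelled here as a between-lab standard
deviation `tau`. Second, a few results may sit far from the bulk, or the
whole configuration may be skewed, without any substantive reason to
discard anything. Which laboratories to include in the KCRV is a
substantive decision made upstream; the statistics must then cope with
whatever set was retained. Excluded laboratories still receive degrees of
equivalence.

## The model and the tree

All estimators in this package are versions of the random-effects model

```
x_j = mu + lambda_j + epsilon_j ,
```

where `mu` is the measurand value, `lambda_j` is a laboratory effect with
mean 0 and standard deviation `tau`, and `epsilon_j ~ N(0, sigma_j)` is
measurement error. A reported uncertainty with finite `nu_j` is treated as
an *estimate* of `sigma_j` (via the data term
`nu_j u_j^2 / sigma_j^2 ~ chi-squared(nu_j)`); an infinite `nu_j` pins
`sigma_j = u_j`.

Three gating tests route a study to one of five estimators:

1. **Mutual consistency** — Cochran's Q against chi-squared with `n - 1`
   degrees of freedom. Consistent studies go to node 2, inconsistent to 3.
2. **Gaussian shape** of the standardized values `(x_j - median(x))/u_j` —
   Shapiro-Wilk below 8 labs, otherwise both Shapiro-Wilk and
   Anderson-Darling with the smaller p-value deciding. Gaussian shape
   selects the *adaptive weighted average*; otherwise the *weighted
   median*.
3. **Symmetry** of the measured values (Miao-Gel-Gastwirth statistic with
   a bootstrap null): asymmetry selects the *hierarchical skew-Student +
   Gauss* model; symmetric studies go to node 4.
4. **Gaussian shape** again: *hierarchical Gauss + Gauss* if Gaussian,
   else *hierarchical Laplace + Gauss*.

The recommendation is advisory. `kc_decide()` returns a full trace (every
p-value, size and branch); `kc_estimate()` accepts any leaf directly, and
`kc_run(force_leaf = ...)` overrides the routing in the full pipeline.

### Test sizes

Cochran's Q runs at a generous default size of 0.10: failing to detect
dark uncertainty is costlier than falsely declaring it. Symmetry and
Gaussian shape default to 0.05. `decision_config(bonferroni = TRUE,
overall_alpha = a)` replaces all three by `a/3`, the conservative
correction for the at-most-three tests a traversal visits; we apply it to
all three nominal sizes regardless of which nodes are actually visited,
since the tests are applied sequentially and a path-dependent correction
would be anti-conservative. A p-value exactly equal to the size does not
reject.

Because the gating tests lose power quickly for small `n`, traversals
attach warnings below 5 labs (all tests), below 10 (shape tests), and
below 30 (symmetry); and whenever Q fails to reject while the Q-profile
interval for `tau` still reaches beyond twice the typical reported
uncertainty — homogeneity "accepted" on weak evidence.

## The five estimators

**Adaptive weighted average.** Weighted mean with weights
`1/(u_j^2 + tau_hat^2)`, `tau_hat` the DerSimonian-Laird moment estimate
(exactly the plain weighted mean when `tau_hat = 0`). Uncertainty comes
from a parametric bootstrap: fresh `lambda* ~ N(0, tau_hat)`, errors with
scale `u_j` — redrawn as `u_j sqrt(nu_j / chi2_{nu_j})` for labs with
finite degrees of freedom — then `tau` and the mean re-estimated per
replicate. The reported uncertainty is the larger of the bootstrap and
internal (`(sum 1/u_j^2)^{-1/2}`) evaluations, since the bootstrap value
can only fall below the internal one by Monte Carlo accident.

**Weighted median.** Weights `1/u_j^2`. We invert the weighted empirical
distribution function with linear interpolation between the jump points;
this smooths the otherwise piecewise-constant estimator and is the
convention of the implementation used in the published analyses of these
data (the order-statistic minimiser of the weighted L1 loss is available
with `interpolate = FALSE`). The reported consensus is the bootstrap mean
of the replicate medians (the bagged estimate). We chose bagging over the
`2m - mean(m*)` bias flip after observing that the interpolated weighted
median's bootstrap distribution is strongly discrete: the bagged value is
the smoother and, on the zinc comparison below, is the value the published
analysis reports. The raw point estimate and the bootstrap bias are kept
in the result object. Resampling is nonparametric (pairs `(x_j, u_j)`)
for 15 or more included labs, parametric below — the published analyses
used nonparametric at `n = 19` and parametric at `n = 4`, and 15 separates
those regimes.

**Three Bayesian hierarchical models** differing only in the effects
family: Gaussian, Laplace (scale `tau/sqrt(2)` so that `tau` is always the
effects' sd), and the Azzalini skew-Student, constrained to mean zero by
the location offset `xi = -omega delta b(nu)` and parameterized so that
`tau` is again the sd (which requires `nu > 2`; the prior truncates at 3).
The KCRV is the posterior mean of `mu`, its uncertainty the posterior sd.

### Priors

Defaults are weakly informative and data-scaled:
`mu ~ N(median(x), (1e5 mad(x))^2)`; `tau ~` half-Cauchy(`mad(x)`);
`sigma_j ~` half-Cauchy(`median(u)`) where `nu_j` is finite;
`alpha ~ N(0, 4^2)`; `nu ~ Gamma(2, 0.2)` truncated to `[3, Inf)`. The
skewness prior deserves comment: with 10-ish laboratories the slant of a
skew-t is weakly identified, and the prior scale materially shapes the
posterior. `N(0, 4^2)` keeps the prior mass over slants that produce
realistic skewness (the standardized skewness of a skew-t saturates
quickly in `|alpha|`) while still letting the data push `alpha` to either
side; much wider scales let the posterior wander to slants that are
observationally near-equivalent but numerically extreme. The Gamma(2, 0.2)
tail-dof prior (mean 10) covers everything from near-Cauchy tails to
near-Gaussian ones without favouring degenerate corners. All scales are
configurable via `hier_model_spec()`.

### MCMC

Models are fitted with JAGS through rjags. Defaults: 4 chains, 3000
adaptation + 3000 burn-in iterations, 2500 retained draws per chain with
thinning 4. Thinning matters here: the location mixes slowly against
centred Laplace effects, and `tau` against non-centred Gaussian effects,
so we parameterize each family in the regime where its leaf operates
(Gaussian effects non-centred, Laplace centred) and thin the rest of the
autocorrelation away. Convergence is gated on split-Rhat <= 1.05 and
effective sample size >= 400 for `mu` and `tau`; failing the gate raises a
warning carrying the diagnostics, not an error, since the draws may still
be useful for diagnosis. The half-life comparison below is the one
shipped example that needs a heavier run (`thin = 12`, `warmup = 5000`)
to pass the gate.

## Degrees of equivalence

`compute_does()` covers all `N` laboratories. `D_j = x_j - KCRV` exactly;
`U95(D_j)` is the half-width of the central 95 % interval of replicate
differences built from the retained draws, with a *fresh* effect
`lambda*` per replicate — a lab is flagged when its value lies beyond the
range the fitted model allows for a lab like it, which is what propagates
dark uncertainty into the DoEs. Where a parametric bootstrap retained the
per-lab replicate data (the adaptive weighted average and the parametric
weighted median), included labs reuse their own replicate datum, so the
estimator-datum correlation is inherited exactly; everywhere else the
replicate value is generated fresh and compared against the reported KCRV,
which adds the consensus uncertainty without any correlation credit — the
conservative direction. In the no-dark-uncertainty, infinite-dof limit an
excluded lab's `U95` reduces to the textbook
`1.96 sqrt(u_j^2 + u(KCRV)^2)`, a closed form the test suite checks.

## The symmetry test's bootstrap

The statistic is `T = (mean - median) / J` with
`J = sqrt(pi/2) mean(|x - median|)`, applied to the measured values (the
shape tests, by contrast, see the standardized values — the two families
of tests deliberately look at different aspects of the data). The null
distribution resamples from the sample symmetrized about its median,
`{x_j - m} U {-(x_j - m)}`, and we draw a full bootstrap sample *of the
symmetrized set's own size* (2n) per replicate. We fixed this convention
by verifying it against the published p-values of four worked comparisons
(0.22, 0.007, 0.02 within ±0.03, and the routing decisions they imply);
resampling only n per replicate reproduces none of them and flips two
routings. The cost is a mildly anticonservative size — about 0.08-0.09 at
`n = 10` for nominal 0.05, approaching nominal as `n` grows — which the
test suite documents as a band rather than asserting strict nominality,
and which slightly favours the skew-Student leaf on borderline samples.
One published value (0.13 on a 4-lab comparison) resisted every
reconstruction we tried and is recorded as an open discrepancy. Bootstrap
p-values are bit-reproducible given `(seed, n_boot)`; the default
`n_boot = 10000` stabilises them to about ±0.005.

## The synthetic generator

`generate_kc()` draws reported uncertainties log-uniformly on `u_range`
(mimicking the order-of-magnitude spread across real participants),
effects from the configured family scaled to `sd = tau_true`, and Gaussian
errors. Under a finite-dof policy the *reported* `u_j` is additionally
redrawn as `sigma_j sqrt(chi2_nu / nu)`, emulating uncertainty statements
that are themselves estimates. It emulates exactly the random-effects
structure the estimators assume — independent labs, Gaussian errors, a
single effects family — and none of the pathologies of real comparisons
(correlated methods, drifting travelling standards, misreported
uncertainties). Passing recovery tests on this generator therefore shows
the machinery is self-consistent, not that the model is right for any
particular comparison.

Two power facts about the tree, measured on this generator, are worth
knowing. Homogeneous Gaussian data land in the two homogeneous leaves
about 90 % of the time at size 0.10, as designed. But Laplace-distributed
effects are reliably recognised as heterogeneous and symmetric while the
Gaussian-shape node detects their heavy tails only ~1/3 of the time even
at `n = 50`: the Laplace leaf is reached in a minority of traversals, its
Gaussian sibling absorbing the rest. That is a power limit of
Shapiro-Wilk/Anderson-Darling against Laplace tails, not a defect of the
routing; the practical consequence is mild because the two leaves'
consensus values rarely differ much when the shape test cannot tell them
apart.

## Worked example

```{r k45, eval = FALSE}
st <- kc_fixture("K45")
report <- kc_run(st, seed = 1)
report
autoplot(report$doe)
```

The tin-in-tomato-paste comparison (4 included labs, one lab reporting
`k = 2.45`, i.e. 6 effective degrees of freedom) is homogeneous
(Q = 3.92, p = 0.27) and Gaussian (Shapiro-Wilk p = 0.92), so the tree
recommends the adaptive weighted average: KCRV 226.5 mg/kg, with a
bootstrap uncertainty (~0.66 mg/kg) clearly above the internal 0.5 mg/kg
— the dark-uncertainty estimate `tau_hat` = 0.601 mg/kg and the 6-dof lab
both inflate it. The Q-profile 95 % interval for `tau`, (0.0, 8.8) mg/kg,
is a reminder that four labs cannot pin `tau` down, which is why the
adaptive (rather than plain) weighted average is used even here.

## Numerical choices and degenerate inputs

* Q-profile roots are bracketed on `[0, 100 max u_j]` and solved by
  bisection to relative tolerance 1e-8; `Q(tau)` is strictly decreasing,
  so the bracket is valid whenever a root exists, and a lower bound that
  would be negative truncates to 0.
* `dof_from_coverage_factor()` inverts the two-sided Student-t quantile by
  root finding and returns `Inf` within 0.005 of the Gaussian quantile.
* All-equal samples: the MGG statistic is defined as 0 (J = 0), Cochran's
  Q is 0 with p = 1, and the Q-profile interval collapses to [0, 0].
* A weighted median exactly at a cumulative weight of 1/2 returns the
  midpoint of the adjacent values under `interpolate = FALSE`.
* Bootstrap and MCMC draws are seeded explicitly everywhere; reruns with
  the same configuration reproduce every number bit-for-bit.

## Problem sizes used in the checks

The shipped comparisons have 4-21 laboratories. The test suite runs the
bootstrap estimators at 2000-5000 replicates, the MCMC checks at 2 chains
x 1000 thinned draws for simulation studies (50 synthetic studies per
effects family for coverage) and at the full 4 x 2500 defaults for the
worked examples; null-size simulations use 400-2000 replicates. These
sizes keep every Monte Carlo standard error comfortably below the
tolerance being asserted.

## Known limitations

* Only unilateral degrees of equivalence are computed; pairwise DoEs are
  out of scope.
* No alternative heterogeneity estimators (REML, Paule-Mandel) or tests
  (I², H²); the tree as specified uses Cochran's Q and DerSimonian-Laird.
* The skew-Student posterior for a handful of labs is prior-sensitive in
  `alpha` and `nu` (see Priors); report those posteriors with their
  uncertainties, not as point findings.
* The symmetry bootstrap's small-n anticonservatism (above) is inherent
  to the convention that reproduces the published analyses.
* Units are opaque strings; no unit conversion is attempted.
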