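# kcdtree

Decision-tree consensus analysis for interlaboratory key comparisons.

## The problem

In a key comparison, several national metrology institutes measure the
same measurand and each reports a value $x_j$, a standard uncertainty
$u_j = u_c(x_j)$, and sometimes the degrees of freedom $\nu_j$ behind that
uncertainty. The organisers must turn these into a key comparison
reference value (KCRV) with an uncertainty, and into per-laboratory
degrees of equivalence $D_j = x_j - \mathrm{KCRV}$ with expanded
uncertainties $U_{95}(D_j)$ that flag unusual results. The recurring
difficulty is *dark uncertainty*: dispersion of the measured values beyond
what the reported uncertainties allow, modelled as a between-laboratory
standard deviation $\tau$ in the random-effects model

$$x_j = \mu + \lambda_j + \varepsilon_j,\qquad
  \lambda_j \sim F(0, \tau),\quad \varepsilon_j \sim N(0, \sigma_j).$$

This package is for metrologists and interlaboratory-study statisticians.
It routes a study through three gating tests —

1. mutual consistency: Cochran's
   $Q = \sum_j w_j (x_j - \bar x_w)^2$, $w_j = 1/u_j^2$, against
   $\chi^2_{n-1}$;
2. symmetry of the measured values: the Miao–Gel–Gastwirth statistic
   $T = (\bar x - \tilde x)/J$, $J = \sqrt{\pi/2}\,\overline{|x - \tilde x|}$,
   with a bootstrap null built from the symmetrized sample;
3. Gaussian shape of the standardized values $(x_j - \tilde x)/u_j$:
   Shapiro–Wilk and (for $n \ge 8$) Anderson–Darling —

to one of five consensus estimators: the adaptive (DerSimonian–Laird)
weighted average with weights $1/(u_j^2 + \hat\tau^2)$, the weighted
median, or a Bayesian hierarchical model with Gaussian, Laplace, or
mean-zero skew-Student laboratory effects fitted by MCMC (JAGS). Degrees
of equivalence are computed for *all* participants from the retained
bootstrap/posterior draws with fresh effect draws, so dark uncertainty and
the estimator–datum correlation propagate into $U_{95}(D_j)$.

## Worked example

Tin in tomato paste, five laboratories, one of which (UME) was excluded
from the KCRV on substantive grounds, and one of which (KRISS) reported a
coverage factor of 2.45 — i.e. only 6 effective degrees of freedom:

```r
library(kcdtree)
report <- kc_run(kc_fixture("K45"), seed = 1)
report
```

```
== key comparison analysis ==
study: CCQM-K45 [mg/kg]
labs: 5 total, 4 included in KCRV; seed 1

-- gating tests --
           node         test statistic p_value size reject     branch
    homogeneity    cochran_q     3.918  0.2704 0.10  FALSE consistent
 gaussian_shape shapiro_wilk     0.983  0.9197 0.05  FALSE   gaussian

leaf: adaptive_weighted_average (recommended)

KCRV = 226.515 +/- 0.657 mg/kg
dark uncertainty: tau_DL = 0.601, Q-profile 95 % CI (0, 8.78)

-- degrees of equivalence --
   lab value      u        D   U95 included significant
 KRISS 226.3 0.7918  -0.2548 1.795     TRUE       FALSE
   LGC 224.6 1.5000  -1.9148 2.836     TRUE       FALSE
   LNE 230.4 2.9850   3.9052 5.637     TRUE       FALSE
   PTB 227.0 0.7000   0.4852 1.596     TRUE       FALSE
   UME 209.8 3.8000 -16.7148 7.793    FALSE        TRUE
```

The study is homogeneous (Q = 3.92 on 3 degrees of freedom, p = 0.27) and
the standardized values look Gaussian (Shapiro–Wilk p = 0.92), so the tree
recommends the adaptive weighted average. Its KCRV, 226.5 mg/kg, carries a
parametric-bootstrap uncertainty of 0.66 mg/kg — above the internal
$(\sum_j u_j^{-2})^{-1/2} = 0.5$ mg/kg because the DerSimonian–Laird
$\hat\tau = 0.601$ mg/kg and KRISS's 6 degrees of freedom both feed the
bootstrap. UME, excluded from the KCRV, is the one laboratory whose
$|D_j|$ exceeds its $U_{95}$. The wide $\tau$ interval (upper endpoint
8.8 mg/kg) is flagged in the report's warnings: four labs cannot pin dark
uncertainty down.

Individual steps are available as plain functions that take and return
tibbles or small result objects: `kc_study()` / `read_kc_csv()`,
`cochran_q()`, `symmetry_test()`, `gaussian_shape_test()`, `dl_tau()`,
`tau_qprofile()`, `kc_decide()`, `adaptive_weighted_average()`,
`weighted_median_consensus()`, `fit_hier()`, `compute_does()`, with
`tidy()`/`glance()` methods and `autoplot()` for studies and DoE tables.
`generate_kc()` simulates synthetic comparisons with known truth. A thin
command-line wrapper ships in `inst/cli/kcdtree`
(`decide` / `estimate` / `doe` / `synth` / `report`).

Eight published datasets are built in via `kc_fixture()`: `K45`,
`K145_Zn`, `K145_Ni`, `K88`, `K30_1`, `Zn65`, `Sr90`, `CCEM_RF_K25W`.

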