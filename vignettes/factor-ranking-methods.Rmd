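---
title: "Ranking prognostic survival factors: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking prognostic survival factors: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survrank)
```

## The problem

Prognostic scoring systems for patients undergoing curative-intent liver
resection for colorectal metastases often contain a variable that cannot be
recovered retrospectively (a common example is the neutrophil–lymphocyte
ratio, which requires a white-blood-cell differential that many historical
databases lack). Validating or adapting such a score on a retrospective
cohort therefore requires choosing a *replacement* variable. survrank
implements a transparent way to make that choice: rank every candidate
prognostic factor by how strongly it separates survival, using four
complementary engines, and aggregate the per-method ranks.

All four engines operate on *binary* factors coded 0 = favorable,
1 = unfavorable, so that positive Cox coefficients always mean worse
survival. Continuous markers are binarized first (`apply_factors()`):
against a laboratory reference threshold when one exists (e.g. C-reactive
protein ≥ 6 mg/L, albumin ≤ 38 g/L — values exactly at the cutpoint take
the unfavorable side), and at the cohort median when there is none (e.g.
metastasis size). The median rule refuses degenerate splits (all values
identical) rather than silently producing an empty group.

## The four ranking engines

**1. Kaplan–Meier / log-rank.** Each factor's two groups get product-limit
curves $\hat S(t) = \prod_{t_i \le t} (1 - d_i/r_i)$ and are compared by
the two-sample log-rank test: at each distinct event time the observed
events in one group are compared with the hypergeometric expectation, and
$\chi^2 = (\sum_j (O_j - E_j))^2 / \sum_j V_j$ on 1 df. A larger
chi-square earns a better (smaller) rank. Ties between deaths and
censorings at the same time are resolved events-first, the standard
convention.

**2. The integral IS.** For each factor,
$IS = \int_0^{t_{\max}} \big(M(t) - m(t)\big)\,dt$, where $M$ is the curve
of the favorable group and $m$ of the unfavorable group, in months. Both
curves are step functions, so the integral is an exact signed rectangle
sum over the union of their step points — no quadrature error. The
differences are deliberately *signed*: where curves cross, positive and
negative areas cancel, so a factor with overlapping curves scores a
smaller IS than one with cleanly separated curves even when the unsigned
areas agree. This is the property that makes IS a useful sensitivity
measure for ranking; a detected crossing is additionally reported as a
diagnostic. IS is numerically the difference of two restricted mean
survival times (`rmst()`).

**3–4. Univariate and multivariate Cox.** The proportional-hazards model
$h(t \mid x) = h_0(t)\exp(x^\top\beta)$ is fitted by maximising the
partial likelihood with Newton–Raphson from $\beta = 0$, with
step-halving so the log partial likelihood ascends monotonically.
Engine 3 fits each factor alone; engine 4 enters all factors
simultaneously, with nothing added or removed afterwards ("Enter"
strategy). Factors are ranked by descending hazard ratio $\exp(b)$.
Inference is Wald ($z = b/\mathrm{se}$, 95% CI $\exp(b \pm 1.96\,
\mathrm{se})$), matching the convention of the major clinical statistics
packages. A hazard ratio of 1.15 is reported as a 15% excess hazard
(`interpret_hr()`).

## Aggregation and tie-breaking

Every rank column is produced by one deterministic rule (`rank_by()`):
sort by the primary statistic, break ties by the smaller p-value, then
lexicographically by name. The p-value tie-break is needed in practice —
in the reference statistics shipped with the package two factors share a
multivariate hazard ratio of 1.14 and are separated only by p (0.217 vs
0.270).

The final ranking (`final_ranking()`) defaults to the multivariate order:
it reflects each variable's adjusted behaviour with all others held in
the model, and it is the rule that reproduces the reference cohort's
published overall ranks exactly. Because a blend of the IS and
multivariate views is also defensible — IS quantifies impact while
resolving curve overlap — the mean of the IS and multivariate ranks
(ties resolved by the multivariate rank) is available as
`method = "mean_is_multivariate"`. On the reference statistics the two
rules agree on the top four factors and differ only in the middle of the
field.

## The synthetic-cohort generator

The patient-level data behind the reference statistics are confidential,
so the package carries a generator (`generate_cohort()`) reproducing the
*statistical structure* the analysis assumes, making every downstream
stage testable:

* binary factors drawn independently Bernoulli at specified prevalences
  (a latent-Gaussian copula hook exists for correlated factors but
  defaults to independence, since no joint distribution is published);
* event times from the proportional-hazards model with a parametric
  baseline: cumulative hazard $(rt)^{k}\exp(x^\top\beta)$, default shape
  $k = 1$ (exponential). The exponential default was chosen over Weibull
  because no baseline shape is asserted for the real cohort and the
  exponential gives closed forms for test oracles (median $\ln 2 / r$);
  the shape parameter is retained for robustness checks;
* right censoring as the minimum of an administrative horizon and an
  optional independent exponential time.

The study-like default (`study_config()`) uses n = 371, the nine
published prevalences, log hazard ratios equal to the log of the
published multivariate hazard ratios, and a baseline rate *calibrated* so
the marginal median event time is 40 months. Calibration is exact: with
nine binary factors the marginal survival function is the
prevalence-weighted mixture over all $2^9$ covariate patterns, and the
rate is solved by `uniroot()` on that mixture (`calibrate_baseline()`).
Censoring emulates the reference cohort's 2000–2020 accrual with
follow-up to 2022: an administrative horizon of 276 months plus
exponential loss to follow-up with median 139 months (the cohort's median
follow-up). Under these conditions roughly three quarters of subjects
die on study, consistent with a 40-month median OS over a long horizon.

What the generator does **not** emulate: correlation between factors
(surely present in real patients), non-proportional hazards, cohort-era
effects, and informative censoring. Tests that pass on generated data
therefore certify the *procedure* — estimation, integration,
maximisation, ranking — not the clinical validity of any particular
ranking on real data.

## Numerical choices

* **Cox ties.** Breslow's approximation is the default (the convention of
  the clinical packages the reference analysis used); Efron's is
  available by flag, and the two agree exactly on tie-free data.
* **Convergence.** Newton–Raphson stops when the log-partial-likelihood
  change is below 1e-9 or the gradient max-norm below 1e-8, within 50
  iterations. Monotone likelihood (separation) is flagged
  (`converged = FALSE`, diagnostic message), never silently returned;
  zero-variance covariates are rejected as inestimable. No
  regularisation is applied — at the reference scale (nine binary factors,
  n = 371, ~75% events) separation is far away.
* **IS horizon.** `tmax = "auto"` is the *smaller* of the two groups'
  last observed follow-up times, so neither step function is extrapolated
  beyond its support; an explicit horizon is accepted for sensitivity
  analysis, with extrapolation (last value carried forward) flagged.
* **Median CI.** Brookmeyer–Crowley inversion of the pointwise interval
  for $S(t)$ on the log(−log) scale with Greenwood variance — the common
  default in major survival software; the reference analysis does not
  state its method, so this is a documented assumption.
* **Percentages** are rounded half-away-from-zero to one decimal (the
  clinical-table convention; base R's `round()` would give half-to-even).
  C-reactive protein's default cutpoint is 6 mg/L, the accredited-
  laboratory threshold; it is configurable because reference ranges for
  CRP vary between 5 and 6 mg/L across laboratories.
* **p-value display** uses three decimals with `<0.001` flooring, hazard
  ratios two decimals (three below 1).

## Scale of the built-in simulations

The test-suite and acceptance-script simulations use problem sizes chosen
to make Monte-Carlo noise small relative to the tolerances they check:
parameter recovery uses n = 10,000 subjects per replicate (asymptotic SE
of a common-factor coefficient ≈ 0.03) with 100–200 replicates; log-rank
calibration uses 2,000 null replicates of 200 subjects per group, giving
a binomial SE of about 0.005 on the rejection rate; oracle-equivalence
checks use 100 random curve pairs and 25–50 small-cohort maximisations.

## Limitations

The proportional-hazards assumption is never formally tested — the
package exposes the fitted curves for visual checks but implements no
diagnostic test, staying within the scope of the ranking procedure. IS is
treated as a descriptive ranking quantity: no variance or confidence
interval accompanies it, and no censoring-distribution weighting is
applied. Rankings are only as comparable as the binarizations that
produce them; a different cutpoint changes a factor's groups and hence
every statistic downstream.

## A worked run

```{r example}
co <- generate_cohort(study_config(seed = 11))
r <- rank_factors(co)
r
```

The printed table shows, per factor: the log-rank chi-square, the
integral IS in months, the univariate and multivariate hazard ratios with
the multivariate p, the four per-method ranks (R1a = Kaplan–Meier, R1b =
IS, R2a = univariate Cox, R2b = multivariate Cox) and the final rank. On
study-like simulated cohorts the strong true effects (resection margin,
nodal infiltration) surface at the top, while weak ones (fibrinogen,
hazard ratio near 1) fall to the bottom — the qualitative pattern the
procedure exists to detect.
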