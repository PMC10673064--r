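# survrank

Ranking candidate prognostic variables for overall survival after
curative-intent surgery for colorectal liver metastases.

Prognostic scores for this population sometimes contain a variable that a
retrospective database cannot supply (classically the
neutrophil–lymphocyte ratio, which needs a white-cell differential).
Choosing a replacement means asking: *of the candidate factors we do
have, which separates survival most strongly?* survrank answers that by
running four complementary ranking engines over every binary prognostic
factor of a cohort and aggregating their ranks. It is aimed at clinical
biostatisticians validating or adapting survival scores on retrospective
surgical cohorts.

## The four engines

For each factor (coded 0 = favorable, 1 = unfavorable level):

1. **Kaplan–Meier / log-rank** — product-limit curves
   `S(t) = prod over event times t_i <= t of (1 - d_i/r_i)` per group, compared by the
   two-sample log-rank chi-square `(sum(O - E))^2 / sum(V)` with hypergeometric
   moments; larger chi-square, better rank.
2. **Integral IS** — the signed area between the two curves,
   `IS = integral from 0 to tmax of (M(t) - m(t)) dt` in months (`M` = favorable-group
   curve, `m` = unfavorable), computed as an exact rectangle sum over the
   union of step points. Signed differences mean crossing curves cancel
   area, so overlapping curves are ranked lower — the property that makes
   IS a sensitivity measure rather than a plain distance.
3. **Univariate Cox** — one proportional-hazards fit per factor; ranked
   by hazard ratio `exp(b)`.
4. **Multivariate Cox** — all factors entered simultaneously ("Enter"
   strategy, nothing added or removed), Newton–Raphson maximisation of
   the Breslow partial likelihood with Wald inference; ranked by
   adjusted hazard ratio.

The final rank defaults to the multivariate order; a blend of the IS and
multivariate ranks is available (`final_method = "mean_is_multivariate"`).

Because the motivating cohort's patient-level data are confidential, the
package ships (a) the published per-variable summary statistics
(`reference_ranking()`) against which the ranking rules are validated,
and (b) a synthetic-cohort generator (`study_config()`,
`generate_cohort()`) reproducing the cohort's statistical structure —
nine binary factors at the published prevalences, proportional-hazards
event times at the published hazard ratios, an exponential baseline
calibrated to a 40-month median overall survival, and right censoring.

## A worked example

```r
library(survrank)
co <- generate_cohort(study_config(seed = 11))  # study-like synthetic cohort
r  <- rank_factors(co)
r
#> Prognostic factor ranking: 371 subjects, 281 events, 9 factors
#>      variable chi2 IS.months uni.HR multi.HR p.multi R1a R1b R2a R2b final
#>         nodes 17.9      29.0   1.72     1.71  <0.001   1   1   1   1     1
#>        margin  4.5      11.6   1.43     1.70   0.003   4   5   3   2     2
#>  multiplicity 11.6      22.7   1.51     1.46   0.003   2   2   2   3     3
#>           crp  5.9      14.1   1.34     1.31   0.025   3   3   5   4     4
#>    right_side  3.2      13.7   1.37     1.23   0.246   5   4   4   5     5
#>           asa  1.4       6.5   1.15     1.22   0.104   6   7   6   6     6
#>       albumin  1.2       7.2   1.14     1.04   0.740   7   6   7   7     7
#>          size  0.1       1.2   1.03    0.993   0.952   8   8   8   8     8
#>    fibrinogen  0.0      -0.8   1.02    0.984   0.896   9   9   9   9     9
```

Reading the row for `nodes` (nodal infiltration of the primary tumor):
its two Kaplan–Meier curves are 29.0 month-units apart by the integral
IS, the log-rank chi-square is 17.9, and its hazard is 1.71 times higher
with all other factors held in the model — it ranks first by every
engine in this simulated replicate. `fibrinogen`, simulated with a true
hazard ratio near 1, lands at the bottom with a slightly negative IS
(its "unfavorable" group happened to survive marginally better).
Single-cohort ranks are noisy where true effects are close; across
replicates the strong effects (margin, nodes) consistently surface at
the top.

Each engine is also available on its own: `fit_km()`, `logrank_test()`,
`median_survival()`, `rmst()`, `is_integral()`, `fit_cox()`,
`univariate_screen()`, plus cohort I/O (`read_cohort()`,
`apply_factors()`) and a thin command-line wrapper in
`inst/scripts/survrank` (subcommands `simulate`, `km`, `is`, `cox`,
`rank`).

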