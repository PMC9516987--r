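---
title: "Methods: Bayesian spatiotemporal analysis of preschool SDQ scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian spatiotemporal analysis of preschool SDQ scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Routine preschool monitoring with the teacher-rated Strengths and
Difficulties Questionnaire (SDQ) produces, for every assessed child, 25 items
scored 0/1/2 across five domains. The four difficulty domains (emotional,
conduct, hyperactivity, peer) sum to a *total difficulties score* out of 40;
totals of 15 or more indicate a high risk of psychopathology (bands: 0–10
close to average, 11–14 slightly raised, 15–17 high, 18+ very high). A city
that collects these scores over several yearly cohorts wants to know whether
difficulties are rising, whether some electoral wards are systematically
worse than the city average, and whether apparent ward differences are just
demographic composition.

`sdqmap` implements two complementary Bayesian answers and everything around
them: scoring and banding, exclusion filtering, aggregation, descriptive
tables, two model families, spatial diagnostics, DIC model building,
relative-rate and exceedance summaries, choropleth reporting, and a
synthetic-data generator with known ground truth.

## The two models

**Disease mapping (ward-year counts).** The count of high scorers in ward
$j$ and cohort $t$, with exposure $E_{jt}$ assessed children, is modelled

$$Y_{jt} \sim \text{Poisson}(E_{jt}\theta_{jt}), \qquad
\log\theta_{jt} = \beta_0 + (\beta_1 + u_{1j})\,t + u_{0j} + \sum_k \beta_k x_{jkt}$$

with exchangeable ward intercepts $u_{0j} \sim N(0, \sigma^2_{u0})$, an
optional differential linear trend per ward (random slopes $u_{1j}$,
independent or bivariate-normal with the intercepts), and ward-level
covariates: proportion of children outside the expected school-start age
(under 4.5 or over 5.5 years), proportion in the most deprived quintile,
proportion of boys. This is the classical spatiotemporal formulation with a
shared linear trend plus area-specific departures.

Although the count model is often written with a single area index, the
cohort covariate implies ward-by-year observations; the model is fitted on
the full ward × cohort grid with $E_{jt}$ the children assessed in that
cell. Cohort is coded $t = \text{year} - \text{first year}$, so
$\exp(\beta_0)$ is the baseline high-score rate in the first cohort year.

**Multilevel (individual scores).** The total score of child $i$ in
preschool $k$ and ward $j$ is modelled zero-inflated negative binomial
(ZINB):

$$Y_{ijk} \sim \text{ZINB}(\lambda_{ijk}, p, r), \qquad
\log\lambda_{ijk} = \beta_0 + (\beta_1 + v_{1j})\,t + \alpha_k + v_{0j} + \beta_\phi x_i$$

Normative SDQ data are right-skewed with many exact zeros and variance far
above the mean, hence the structural-zero mixture (weight $p$) on a negative
binomial with mean $\lambda$ and overdispersion $r$. The zero inflation is a
genuine mixture, not a hurdle: $P(0) = p + (1-p)\,\text{NB}(0)$. $p$ and $r$
are global scalars; nothing in the data identifies covariate effects on the
zero component separately. Preschool effects $\alpha_k$ and ward effects
$v_{0j}$ are **cross-classified**: a preschool draws children from its home
ward and, with small probability, adjacent wards, so neither factor nests
the other. Individual covariates are sex, age centred on 59 months and
squared (one quadratic term — difficulties are elevated at both ends of the
school-start age range, so a linear term is deliberately absent), and
deprivation quintile as four dummies against the least-deprived reference.

**Priors.** Fixed effects get $N(0, 1000)$; every random-effect precision
gets $\Gamma(1, 0.0005)$, the classic weakly-informative disease-mapping
default. Both are configurable via `prior_config()`. The zero-inflation
weight gets $U(0,1)$ and the overdispersion $U(0.01, 50)$.

**Inference.** Gibbs/slice MCMC via JAGS (`rjags`). Any backend delivering
joint posterior draws would satisfy the same contract; the package's own
code builds the model strings, seeds each chain deterministically, recentres
the random-effect draws, and computes deviance, DIC, relative rates and
exceedance probabilities from the raw draws.

## Identifiability: the sum-to-zero sweep

With a free intercept and exchangeable random intercepts, only
$\beta_0 + \overline{u_0}$ is identified. After sampling, every draw is
recentred: the mean of each random-effect block is subtracted and added to
the intercept (slope means are swept into the overall trend). This imposes
the sum-to-zero constraint exactly, draw by draw; the recovered intercept
estimand is then the generating intercept *plus the realised mean of the
drawn effects*, which is what recovery tests compare against (the generator
records every drawn effect in its truth ledger).

## Relative rates and exceedance

All effects are reported exponentiated as relative rates (RR): an RR of 1.10
is a 10% higher rate (disease mapping) or a 10% higher average score
(multilevel). Ward and preschool RRs ($e^{u_{0j}}, e^{v_{0j}}, e^{\alpha_k}$)
compare each area/institution with the average. Uncertainty is summarised by
the exceedance probability $\Pr(\text{RR} > 1)$ computed by direct counting
over the posterior draws; values of 0.8 or more flag high-certainty
elevations, and the exceedance choropleth uses a binary emphasis break at
exactly 0.8.

## Spatial structure decision

Ward effects are *unstructured* (exchangeable) by default. The decision is
empirical: simulation-based residuals are aggregated by ward and tested with
Moran's I under queen contiguity (areas sharing a border segment or corner
are neighbours), using binary weights and permutation inference — with only
~21 areas the normal approximation is not trustworthy. The two-sided
permutation p-value is $(1 + \#\{|I_b - E[I]| \ge |I_{obs} - E[I]|\})/(B+1)$
with $E[I] = -1/(n-1)$. A non-significant screen (threshold 0.05,
configurable) keeps the unstructured prior. When the screen does show
residual spatial correlation, `dm_spec(structured = TRUE)` switches the ward
intercepts to a proper conditional autoregressive prior (precision
$\tau(D - 0.95W)$ on the queen-contiguity graph, the 0.95 keeping the
precision proper while approximating the intrinsic version); it is off by
default and never part of the headline model.

Residuals are randomized-PIT: for each observation, `n_sim`
posterior-predictive replicates are simulated (each conditioning on a random
posterior draw of *all* parameters) and the observation's rank among them,
with a uniform draw inside the tie interval, gives a residual that is
marginally Uniform(0,1) under a correctly specified model — the standard
construction for discrete outcomes, implemented natively and seeded.

## DIC model building

$\text{DIC} = \bar D + p_D$, $p_D = \bar D - D(\bar\theta)$, computed from
the package's own pointwise log-likelihood evaluators (Poisson and ZINB) on
the stored draws; for the mixture model the deviance is the *conditional*
deviance at the posterior means of coefficients, effects, $p$ and $r$ (the
DIC focus for mixtures is a genuine choice; conditional is the one
implemented and documented, so absolute DIC values are comparable only
within this package).

Forward building adds candidate terms in a fixed order (slopes, then
covariates for the count model; preschool effect, slopes, then covariates
for the multilevel model) and keeps:

* a **covariate** unless dropping it improves DIC by more than `dic_tol`
  (default 1) — covariates whose removal does not improve fit stay;
* a **random term** only if it improves DIC by more than `dic_tol_random`
  (default 5). DIC differences below about 5 are conventionally not
  meaningful, and the conditional-focus DIC lets spurious random effects
  absorb a few deviance points by chance; genuine random structure in these
  models improves DIC by tens to hundreds, so the margin costs nothing.

## Convergence

Gelman–Rubin $\hat R$ per parameter across chains (2+ chains needed). Fits
with any $\hat R$ above `rhat_threshold` (default 1.05) are flagged and
summaries are withheld unless forced. With $\Gamma(1, 0.0005)$ precision
priors and ~21 areas, the variance-component $\hat R$ hovers just above 1.01
at practical chain lengths while every rate summary is stable; 1.05 avoids
spuriously withholding summaries and remains configurable for stricter use.

## The synthetic-data generator

The real data behind this design are not public, so the generator defines
the study conditions: about 35,000 children over 8 yearly cohorts
(2010–2017), 21 wards, 180 preschools, 51% boys, ward-varying deprivation
composition (per-ward Dirichlet around the city-wide marginal,
concentration 10), and ages drawn uniformly in months within the four
school-start bands (weights 6.0/46.8/43.5/3.7%). Scores are drawn from
exactly the ZINB multilevel model above. Default generating values are the
published adjusted posterior means of a comparable city-wide analysis:
intercept rate 4.079, boys × 1.370, cohort × 1.008 per year, age
× 1.003 per squared month, deprivation contrasts 1.115/1.174/1.234/1.243,
preschool variance 0.062, ward variance 0.013. That analysis did not report
fitted zero-inflation or overdispersion, so `p = 0.15` and `r = 2` were
chosen once to reproduce the descriptive skew (median 4, IQR 1–9, ~9%
scoring 15+) and are not revisited.

Design choices worth knowing:

* **Support.** Unbounded ZINB draws above 40 are rejected and redrawn,
  keeping the fitted family on the valid SDQ support. If the generating
  means ever imply average truncated mass above 1%, a warning is logged.
* **Ward populations** are multinomial with configured weights (default:
  normalised Gamma(5,1), roughly two-fold variation) — exposure varies by
  ward but no distribution is prescribed for it.
* **Geography** is a binary-space-partition tessellation of the unit square
  (or a regular grid); queen adjacency is computed from rectangle contact
  and can be independently recomputed from the emitted GeoJSON polygons by a
  shared-boundary-or-point test (`adjacency_from_polygons()`).
* **Items.** When item-level data are requested, the drawn total is
  distributed over the 40 unit slots of the 20 difficulty items and
  reverse-scored items are emitted on the raw scale, so scoring the items
  reproduces the total exactly.
* The generator emulates the *generative structure* the models assume. It
  does not emulate informative missingness, measurement drift between
  questionnaire versions, rater effects beyond the preschool intercept, or
  real ward shapes — so passing recovery tests shows the estimation
  machinery is correct, not that the models are adequate for any particular
  real data set.

## Scoring conventions

Item-to-domain mapping and the five reverse-scored items follow the
published scoring syntax and live in a configuration table
(`sdq_item_map()`), not in code. Partial forms are prorated (domain =
rounded mean × 5 when ≥3 of 5 items answered, else the total is missing);
the data behind this design never specify partial handling, so the standard
convention is used and flagged via the `prorated` column. Presentation
percentages round half-up to one decimal; quartiles use lower
nearest-rank interpolation so integer scores give integer IQRs. Age bands
are half-open, `[4,4.5) … [5.5,6]`, partitioning the eligible range; the
exclusion rule keeps exactly ages 4–6 at school entry.

## Degenerate inputs

* All-zero outcome → the zero-inflation weight is unidentifiable; the fit
  aborts with a diagnostic.
* One ward (or one preschool) → the corresponding variance component is
  dropped with a warning.
* Constant ward medians → the Gaussian median-outcome variant returns the
  degenerate zero-heterogeneity fit analytically (the residual precision is
  unbounded and MCMC would be meaningless).
* A single cohort cannot identify the linear trend; the median variant
  refuses to fit.
* `E = 0` ward-years are rejected.

## Problem sizes used by the test and acceptance suites

All empirical claims in the package are recomputed by the tests or the
acceptance script, at sizes chosen as the package's own desk-scale defaults:
geometry and scoring oracles run at full published scale (41,128-record
exclusion fixture); disease-mapping recovery uses 21 wards × 8 cohorts with
~209 children per cell over 5–10 seeds; multilevel recovery uses 1,500–2,500
children, 21 wards, 60 preschools per seed over up to 10 seeds with short
chains; calibration uses 80 desk-scale replicates for trend coverage and 200
replicates for Moran null uniformity. Posterior-mean recovery at these sizes
is well inside the tolerances asserted, and the identifiable intercept is
compared against the ledger-adjusted truth as described above.

## Known limitations

* Conditional-focus DIC: absolute values are not comparable with marginal
  DIC implementations.
* Under the unstructured default the models report heterogeneity, not
  spatial smoothing; the proper-CAR flag exists for the structured case but
  is not tuned for it (no BYM convolution, fixed autocorrelation 0.95).
* JAGS updates the latent zero indicators child by child; fits at the full
  35,000-child scale take correspondingly longer than the desk-scale
  defaults used in tests.
* Exceedance flags at 0.8 are decision aids, not multiplicity-corrected
  tests.
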