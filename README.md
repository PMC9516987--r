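# sdqmap

Bayesian spatiotemporal analysis of preschool **Strengths and Difficulties
Questionnaire (SDQ)** total difficulties scores across the small areas of a
city — for epidemiologists, child-health analysts and public-health teams
who hold routine child-level SDQ collections and want to know *whether
difficulties are rising, where they are concentrated, and how much of the
geography is just demographics*.

The package implements two complementary models over the same data:

**Disease mapping** — counts of high scorers (total ≥ 15) per ward j and
cohort t, with the assessed children as exposure:

```
Y_jt ~ Poisson(E_jt · θ_jt)
log θ_jt = β0 + (β1 + u1j)·t + u0j + Σk βk·x_jkt,   u0j ~ N(0, σ²u0)
```

**Multilevel** — each child's total score, zero-inflated negative binomial,
with cross-classified preschool and ward random effects:

```
Y_ijk ~ ZINB(λ_ijk, p, r)
log λ_ijk = β0 + (β1 + v1j)·t + αk + v0j + βφ·x_i
αk ~ N(0, σ²α),  v0j ~ N(0, σ²v0)
```

Around them: SDQ item scoring/banding with configurable item maps, the
five-criterion exclusion filter, ward-year aggregation, descriptive tables,
Moran's I permutation tests on queen-contiguity weights, randomized-PIT
residual diagnostics, DIC forward model building, relative-rate (RR) and
exceedance-probability summaries (`Pr(RR > 1) ≥ 0.8` flags high-certainty
elevations), choropleth maps, an end-to-end pipeline, and a synthetic-data
generator with a recorded ground-truth ledger for parameter-recovery
testing. Inference is MCMC via JAGS (`rjags`).

## Worked example

Simulate a city (21 wards, 60 preschools, 8 cohorts), filter, describe, fit
the disease-mapping model and check the spatial structure decision:

```r
library(sdqmap)

geo      <- simulate_geography(n_wards = 21, seed = 1)
children <- simulate_children(geo, n_children = 8000, n_preschools = 60, seed = 2)
retained <- apply_exclusions(children)

describe_sdq(retained, by = "sex")
#>   group_var level      N n_high pct_high median   q25   q75
#> 1 total     total   8000    667      8.3      4     1     9
#> 2 sex       female  3890    218      5.6      4     1     7
#> 3 sex       male    4110    449     10.9      5     2    10
```

8.3% of simulated children are high scorers (the generator is calibrated to
~9%), and boys are roughly twice as likely to score high as girls — the
`pct_high` column is the per-group percentage at one decimal place.

```r
counts <- aggregate_ward_year(retained)
fit    <- fit_dm(counts, dm_spec(), n_chains = 2, seed = 3)
glance(fit)
#>   n_obs n_wards D_bar   p_D   DIC max_rhat converged n_draws
#> 1   168      21  647.  19.2  666.     1.00 TRUE         4000

rr <- rr_summaries(fit)
dplyr::filter(rr, type == "fixed")
#>   term      type      rr  rr_lo  rr_hi exceedance flagged
#> 1 intercept fixed 0.0738 0.0632 0.0849      0     FALSE
#> 2 cohort    fixed 1.00   0.969  1.03       0.518  FALSE
```

The baseline high-score rate is about 7.4 per 100 children in the first
cohort; at this sample size the small generating cohort trend is not
distinguishable from flat (its credible interval spans 1). Ward RRs compare
each ward with the city average; wards whose exceedance probability reaches
0.8 are flagged:

```r
dplyr::slice_max(dplyr::filter(rr, type == "ward"), rr, n = 3)
#>   term    type     rr rr_lo rr_hi exceedance flagged
#> 1 ward_4  ward   2.39  1.78  3.11          1 TRUE
#> 2 ward_18 ward   1.90  1.41  2.48          1 TRUE
#> 3 ward_21 ward   1.72  1.33  2.17          1 TRUE
```

(Unadjusted ward effects fold in demographic composition and preschool
effects; adding ward covariates via `dm_spec(covariates = ...)` or running
`forward_build_dm()` shows how much of this is explained away.)

Scaled residuals aggregated by ward show no spatial correlation, supporting
the unstructured (exchangeable) ward-effect prior:

```r
res <- scaled_residuals(fit, n_sim = 200, seed = 4)
residual_moran_screen(res$residual, res$ward_id, geo$adjacency, seed = 5)
#>        I expected_I p_value n_permutations  seed spatial_structure
#> 1 -0.205      -0.05   0.216            999     5 unstructured
```

The individual-level model runs the same way (`fit_ml()`, `tidy()`,
`rr_summaries()`, per-preschool RRs included), and `run_pipeline()` drives
simulate → describe → fit-dm → fit-ml → diagnose → report from one
configuration, including the sensitivity variants (always-participating
preschools; ward-median outcome).

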