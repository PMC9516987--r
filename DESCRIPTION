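Package: sdqmap
Title: Bayesian Spatiotemporal Mapping of Preschool SDQ Total Difficulties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing geographic and temporal trends in preschool
    Strengths and Difficulties Questionnaire (SDQ) total difficulties scores
    across the small areas of a city. Implements SDQ item scoring and banding,
    exclusion filtering, ward-by-cohort aggregation and descriptive tables; a
    Bayesian Poisson disease-mapping model of high-score counts with a linear
    cohort trend, unstructured ward intercepts and optional differential
    slopes; a Bayesian zero-inflated negative binomial multilevel model of
    individual scores with cross-classified preschool and ward random effects;
    Moran's I permutation tests on queen-contiguity weights, simulation-based
    randomized PIT residuals, DIC model building, relative-rate and exceedance
    probability summaries, and choropleth reporting. Includes a synthetic-data
    generator with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
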