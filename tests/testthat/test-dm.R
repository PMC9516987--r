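# disease-mapping fits here use 2 short chains; study-scale recovery runs in
# the acceptance suite

test_that("MCMC matches the conjugate Gamma-Poisson posterior for a single rate", {
  set.seed(1)
  E <- rpois(12, 150) + 1
  theta_true <- 0.08
  Y <- rpois(12, E * theta_true)
  fit <- fit_rate_conjugate(Y, E, a = 2, b = 10, n_iter = 8000, seed = 2)
  sh <- fit$closed_form[["shape"]]; rt <- fit$closed_form[["rate"]]
  expect_equal(mean(fit$draws), sh / rt, tolerance = 0.02)
  expect_equal(quantile(fit$draws, 0.025)[[1]], qgamma(0.025, sh, rt), tolerance = 0.03)
  expect_equal(quantile(fit$draws, 0.975)[[1]], qgamma(0.975, sh, rt), tolerance = 0.03)
})

test_that("doubling the exposure shifts the intercept by -log 2 and leaves RRs alone", {
  counts <- make_dm_counts(n_wards = 10, n_cohorts = 4, E_mean = 300, seed = 3)
  f1 <- fit_dm(counts, n_chains = 2, n_iter = 1500, seed = 4)
  counts2 <- dplyr::mutate(counts, E = E * 2L)
  f2 <- fit_dm(counts2, n_chains = 2, n_iter = 1500, seed = 4)
  b0_1 <- mean(f1$draws[, "b0"]); b0_2 <- mean(f2$draws[, "b0"])
  expect_equal(b0_2 - b0_1, -log(2), tolerance = 0.05)
  rr1 <- rr_summaries(f1, force = TRUE); rr2 <- rr_summaries(f2, force = TRUE)
  w1 <- rr1$rr[rr1$type == "ward"]; w2 <- rr2$rr[rr2$type == "ward"]
  expect_equal(w1, w2, tolerance = 0.05)
})

test_that("ward effects are constrained to sum to zero in every draw", {
  counts <- make_dm_counts(n_wards = 8, n_cohorts = 4, seed = 5)
  fit <- fit_dm(counts, n_chains = 2, n_iter = 1000, seed = 6)
  u0 <- fit$draws[, grep("^u0\\[", colnames(fit$draws))]
  expect_lt(max(abs(rowSums(u0))), 1e-10)
})

test_that("a null simulation is recovered: trend CrI covers 1 and ward variance is small", {
  covers <- 0
  for (seed in 1:8) {
    counts <- make_dm_counts(n_wards = 12, n_cohorts = 5, E_mean = 250,
                             b1 = 0, sigma2_u0 = 0, seed = 100 + seed)
    fit <- fit_dm(counts, n_chains = 2, n_iter = 1200, n_burnin = 600,
                  seed = seed)
    rr <- rr_summaries(fit, force = TRUE)
    tr <- rr[rr$term == "cohort", ]
    if (tr$rr_lo <= 1 && tr$rr_hi >= 1) covers <- covers + 1
    expect_lt(mean(fit$draws[, "sigma2_u0"]), 0.02)
  }
  expect_gte(covers, 7)
})

test_that("RR exceedance equals direct draw counting and 0.8 flags high certainty", {
  counts <- make_dm_counts(n_wards = 10, n_cohorts = 5, sigma2_u0 = 0.1, seed = 7)
  fit <- fit_dm(counts, n_chains = 2, n_iter = 1500, seed = 8)
  rr <- rr_summaries(fit, force = TRUE)
  u0 <- fit$draws[, grep("^u0\\[", colnames(fit$draws))]
  for (j in c(1, 5, 10)) {
    brute <- mean(exp(u0[, j]) > 1)
    expect_equal(rr$exceedance[rr$term == sprintf("ward_%d", j)], brute)
  }
  expect_equal(rr$flagged, rr$exceedance >= 0.8)
  # degenerate posteriors: all-positive draws give exceedance 1, symmetric ~0.5
  pos <- matrix(abs(rnorm(1000)), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(sdqmap:::rr_from_draws(pos, "x", "x", "t")$exceedance, 1)
  sym <- matrix(c(rnorm(5000)), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(sdqmap:::rr_from_draws(sym, "x", "x", "t")$exceedance, 0.5,
               tolerance = 0.05)
})

test_that("the median-outcome variant finds no heterogeneity when medians are flat", {
  counts <- make_dm_counts(n_wards = 10, n_cohorts = 4, seed = 9)
  counts$median_score <- 4
  fit <- fit_dm_median(counts, n_chains = 2, seed = 10)
  expect_lt(fit$ward_variance$estimate, 0.03)
  expect_lt(fit$ward_variance$conf.low, 0.005)
})

test_that("the median-outcome variant recovers a known ward variance", {
  set.seed(11)
  u <- rnorm(21, 0, sqrt(0.05))
  grid <- expand.grid(ward_id = 1:21, cohort = 2010:2017)
  counts <- tibble::tibble(ward_id = grid$ward_id, cohort = grid$cohort,
                           Y = 1L, E = 10L,
                           median_score = rnorm(nrow(grid), 4 + u[grid$ward_id], 0.3))
  fit <- fit_dm_median(counts, n_chains = 2, seed = 12)
  expect_equal(fit$ward_variance$estimate, 0.05, tolerance = 0.6)
})

test_that("the structured ward prior fits behind its flag and demands adjacency", {
  counts <- make_dm_counts(n_wards = 9, n_cohorts = 4, seed = 21)
  geo <- simulate_geography(9, layout = "grid", seed = 21)
  spec <- dm_spec(structured = TRUE)
  expect_error(fit_dm(counts, spec, n_chains = 2, n_iter = 400, seed = 22),
               "adjacency")
  fit <- fit_dm(counts, spec, n_chains = 2, n_iter = 800, n_burnin = 400,
                seed = 22, W = geo$adjacency)
  expect_s3_class(fit, "dm_fit")
  expect_true("sigma2_u0" %in% colnames(fit$draws))
  u0 <- fit$draws[, grep("^u0\\[", colnames(fit$draws))]
  expect_lt(max(abs(rowSums(u0))), 1e-10)
})

test_that("degenerate designs are refused with clear errors", {
  counts <- make_dm_counts(n_wards = 6, n_cohorts = 1, seed = 13)
  expect_error(fit_dm_median(counts), "single cohort")
  bad <- make_dm_counts(n_wards = 6, n_cohorts = 2, seed = 14)
  bad$E[1] <- 0L
  bad$Y[1] <- 0L
  expect_error(fit_dm(bad), "E > 0")
})

test_that("tidy and glance expose coefficients, variances and fit metadata", {
  counts <- make_dm_counts(n_wards = 8, n_cohorts = 4, seed = 15)
  counts$prop_boys <- runif(nrow(counts), 0.4, 0.6)
  fit <- fit_dm(counts, dm_spec(covariates = "prop_boys"),
                n_chains = 2, n_iter = 1200, seed = 16)
  td <- tidy(fit)
  expect_true(all(c("intercept", "cohort", "prop_boys", "sigma2_u0") %in% td$term))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  te <- tidy(fit, exponentiate = TRUE)
  expect_equal(te$estimate[te$term == "cohort"],
               mean(exp(fit$draws[, "b1"])))
  g <- glance(fit)
  expect_equal(g$DIC, fit$dic$DIC)
  expect_equal(g$DIC, g$D_bar + g$p_D)
  expect_true(is.logical(g$converged))
})
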