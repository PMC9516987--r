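# DIC-guided forward building; qualitative structure checks at desk scale

test_that("an empty candidate list yields the base-model ledger only", {
  counts <- make_dm_counts(n_wards = 8, n_cohorts = 4, seed = 1)
  fb <- forward_build_dm(counts, candidates = character(), seed = 2,
                         n_chains = 2, n_iter = 800, n_burnin = 400)
  expect_equal(nrow(fb$ledger), 1L)
  expect_equal(fb$ledger$term, "base")
  expect_false(fb$spec$include_slopes)
  expect_length(fb$spec$covariates, 0)
})

test_that("random slopes are dropped when the generating slope variance is zero", {
  counts <- make_dm_counts(n_wards = 15, n_cohorts = 8, E_mean = 250,
                           b1 = log(1.03), sigma2_u0 = 0.02, seed = 3)
  fb <- forward_build_dm(counts, candidates = "slopes", seed = 4,
                         n_chains = 2, n_iter = 1200, n_burnin = 600)
  row <- fb$ledger[fb$ledger$term == "slopes", ]
  expect_false(row$retained)
  expect_false(fb$spec$include_slopes)
  # the DIC penalty for the useless slopes is small either way
  expect_lt(abs(row$dic_with - row$dic_without), 15)
})

test_that("a strong ward covariate is retained", {
  set.seed(5)
  counts <- make_dm_counts(n_wards = 15, n_cohorts = 6, E_mean = 300,
                           sigma2_u0 = 0.005, seed = 5)
  counts$prop_boys <- runif(nrow(counts), 0.3, 0.7)
  counts$Y <- rpois(nrow(counts), counts$E * exp(log(0.06) + 2 * counts$prop_boys))
  fb <- forward_build_dm(counts, candidates = "prop_boys", seed = 6,
                         n_chains = 2, n_iter = 1200, n_burnin = 600)
  expect_true(fb$ledger$retained[fb$ledger$term == "prop_boys"])
  expect_true("prop_boys" %in% fb$spec$covariates)
})

test_that("a pure-noise covariate does not materially improve DIC", {
  ok <- 0
  for (seed in 1:10) {
    counts <- make_dm_counts(n_wards = 12, n_cohorts = 5, E_mean = 200,
                             b1 = log(1.02), sigma2_u0 = 0.01,
                             seed = 7000 + seed)
    set.seed(seed)
    counts$prop_boys <- runif(nrow(counts), 0.45, 0.55) # unrelated to Y
    base <- fit_dm(counts, n_chains = 2, n_iter = 800, n_burnin = 400,
                   n_adapt = 200, seed = seed)
    noisy <- fit_dm(counts, dm_spec(covariates = "prop_boys"), n_chains = 2,
                    n_iter = 800, n_burnin = 400, n_adapt = 200, seed = seed)
    if (noisy$dic$DIC >= base$dic$DIC || base$dic$DIC - noisy$dic$DIC < 2) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 8)
})

test_that("the multilevel base ledger is returned for empty candidates", {
  geo <- simulate_geography(5, seed = 7)
  rec <- simulate_children(geo, n_children = 400, n_preschools = 8, seed = 8)
  fb <- forward_build_ml(rec, candidates = character(), seed = 9,
                         n_chains = 1, n_iter = 300, n_burnin = 200,
                         n_adapt = 100)
  expect_equal(nrow(fb$ledger), 1L)
  expect_false(fb$spec$include_preschool)
})
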