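# multilevel fits are expensive; unit tests run few, small fits with short
# chains, and the 10-seed study-scale recovery lives in the acceptance suite

test_that("a small simulation recovers the main fixed effects and variance ordering", {
  geo <- simulate_geography(21, seed = 1)
  rec <- simulate_children(geo, n_children = 1500, n_preschools = 60, seed = 2)
  fit <- fit_ml(rec, n_chains = 1, n_iter = 600, n_burnin = 300,
                n_adapt = 200, seed = 3)
  te <- tidy(fit, exponentiate = TRUE)
  expect_equal(te$estimate[te$term == "male"], 1.370, tolerance = 0.1)
  expect_equal(te$estimate[te$term == "cohort"], 1.008, tolerance = 0.05)
  v <- ml_variances(fit)
  expect_gt(v$estimate[v$term == "sigma2_a"], v$estimate[v$term == "sigma2_v0"])
  expect_equal(v$estimate[v$term == "p"], 0.15, tolerance = 0.35)
  expect_equal(v$estimate[v$term == "r"], 2, tolerance = 0.35)
})

test_that("relabelling preschools permutes their effects but nothing else", {
  geo <- simulate_geography(6, seed = 4)
  rec <- simulate_children(geo, n_children = 600, n_preschools = 10, seed = 5)
  spec <- ml_spec(covariates = "sex")
  f1 <- fit_ml(rec, spec, n_chains = 1, n_iter = 500, n_burnin = 300,
               n_adapt = 200, seed = 6)
  # reverse the preschool labels
  rec2 <- dplyr::mutate(rec, preschool_id = 11L - preschool_id)
  f2 <- fit_ml(rec2, spec, n_chains = 1, n_iter = 500, n_burnin = 300,
               n_adapt = 200, seed = 6)
  a1 <- colMeans(f1$draws[, sprintf("a[%d]", 1:10)])
  a2 <- colMeans(f2$draws[, sprintf("a[%d]", 1:10)])
  expect_equal(unname(a1), unname(rev(a2)), tolerance = 0.25)
  expect_equal(mean(f1$draws[, "b0"]), mean(f2$draws[, "b0"]), tolerance = 0.1)
})

test_that("crossed effects sum to zero draw-wise and RR interpretation holds", {
  geo <- simulate_geography(5, seed = 7)
  rec <- simulate_children(geo, n_children = 500, n_preschools = 8, seed = 8)
  fit <- fit_ml(rec, ml_spec(covariates = character()), n_chains = 1,
                n_iter = 400, n_burnin = 250, n_adapt = 150, seed = 9)
  a <- fit$draws[, grep("^a\\[", colnames(fit$draws))]
  v0 <- fit$draws[, grep("^v0\\[", colnames(fit$draws))]
  expect_lt(max(abs(rowSums(a))), 1e-10)
  expect_lt(max(abs(rowSums(v0))), 1e-10)
  # a coefficient held constant at log(1.10) reports RR 1.10 exactly
  const <- matrix(log(1.10), 500, 1, dimnames = list(NULL, "x"))
  rr <- sdqmap:::rr_from_draws(const, "x", "x", "fixed")
  expect_equal(rr$rr, 1.10)
  expect_equal(rr$exceedance, 1)
  # all-negative draws give exceedance 0
  neg <- matrix(-abs(rnorm(500)), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(sdqmap:::rr_from_draws(neg, "x", "x", "t")$exceedance, 0)
  # exceedance equals direct counting over stored draws
  rr_all <- rr_summaries(fit, force = TRUE)
  k <- grep("^preschool_", rr_all$term)[1]
  pid <- sub("preschool_", "", rr_all$term[k])
  col <- sprintf("a[%d]", match(as.integer(pid), fit$pre_levels))
  expect_equal(rr_all$exceedance[k], mean(exp(fit$draws[, col]) > 1))
})

test_that("degenerate inputs fail or degrade as documented", {
  geo <- simulate_geography(4, seed = 10)
  rec <- simulate_children(geo, n_children = 200, n_preschools = 5, seed = 11)
  rec_zero <- dplyr::mutate(rec, total_score = 0L)
  expect_error(fit_ml(rec_zero), "zero")
  rec_one_ward <- dplyr::mutate(rec, ward_id = 1L)
  expect_warning(
    fit <- fit_ml(rec_one_ward, ml_spec(covariates = character()),
                  n_chains = 1, n_iter = 300, n_burnin = 200, n_adapt = 100,
                  seed = 12),
    "one ward")
  expect_false("sigma2_v0" %in% colnames(fit$draws))
  expect_error(fit_ml(dplyr::mutate(rec, total_score = NA_integer_)), "complete")
})

test_that("the plain negative binomial variant drops the zero-inflation parameter", {
  geo <- simulate_geography(4, seed = 13)
  rec <- simulate_children(geo, n_children = 300, n_preschools = 6,
                           truth = sim_truth(p_zero = 0), seed = 14)
  fit <- fit_ml(rec, ml_spec(covariates = character(), zero_inflation = FALSE),
                n_chains = 1, n_iter = 300, n_burnin = 200, n_adapt = 100,
                seed = 15)
  expect_false("p" %in% colnames(fit$draws))
  expect_true("r" %in% colnames(fit$draws))
})
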