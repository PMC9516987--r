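test_that("with no heterogeneity every ward's mean score matches the common ZINB mean", {
  geo <- simulate_geography(6, seed = 1)
  truth <- sim_truth(beta0 = log(4), beta_cohort = 0, beta_male = 0,
                     beta_age_sq = 0, beta_dep = c(0, 0, 0, 0),
                     sigma2_ward = 0, sigma2_preschool = 0,
                     p_zero = 0.15, r_overdisp = 2)
  rec <- simulate_children(geo, n_children = 24000, n_preschools = 18,
                           truth = truth, seed = 2)
  m <- zinb_moments(lambda = 4, p = 0.15, r = 2)
  by_ward <- rec |>
    dplyr::group_by(ward_id) |>
    dplyr::summarise(mean = mean(total_score), n = dplyr::n())
  se <- sqrt(m[["var"]] / by_ward$n)
  expect_true(all(abs(by_ward$mean - m[["mean"]]) < 3.5 * se))
})

test_that("the observed zero fraction matches the mixture zero mass", {
  geo <- simulate_geography(5, seed = 3)
  truth <- sim_truth(beta0 = log(3), beta_cohort = 0, beta_male = 0,
                     beta_age_sq = 0, beta_dep = c(0, 0, 0, 0),
                     sigma2_ward = 0, sigma2_preschool = 0,
                     p_zero = 0.25, r_overdisp = 2)
  n <- 20000
  rec <- simulate_children(geo, n_children = n, n_preschools = 15,
                           truth = truth, seed = 4)
  # independent zero-mass evaluation: p + (1-p) * (r/(r+lambda))^r
  p0 <- 0.25 + 0.75 * (2 / (2 + 3))^2
  obs <- mean(rec$total_score == 0)
  ci <- p0 + c(-1, 1) * qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
  expect_gt(obs, ci[1])
  expect_lt(obs, ci[2])
})

test_that("the default study-scale simulation yields about 9% high scorers", {
  geo <- simulate_geography(21, seed = 5)
  rec <- simulate_children(geo, n_children = 20000, n_preschools = 180, seed = 6)
  expect_equal(mean(rec$total_score >= 15) * 100, 9.0, tolerance = 2 / 9)
  expect_equal(median(rec$total_score), 4)
  expect_true(all(rec$total_score >= 0 & rec$total_score <= 40))
})

test_that("identical config and seed give byte-identical records", {
  geo <- simulate_geography(6, seed = 1)
  r1 <- simulate_children(geo, n_children = 500, n_preschools = 10, seed = 9)
  r2 <- simulate_children(geo, n_children = 500, n_preschools = 10, seed = 9)
  expect_identical(r1, r2)
})

test_that("preschools and wards are cross-classified, not nested", {
  geo <- simulate_geography(10, seed = 2)
  rec <- simulate_children(geo, n_children = 5000, n_preschools = 30, seed = 3)
  wards_per_pre <- rec |>
    dplyr::distinct(preschool_id, ward_id) |>
    dplyr::count(preschool_id)
  pres_per_ward <- rec |>
    dplyr::distinct(ward_id, preschool_id) |>
    dplyr::count(ward_id)
  expect_gt(max(wards_per_pre$n), 1)
  expect_gt(max(pres_per_ward$n), 1)
})

test_that("every drawn random effect is retrievable from the truth ledger", {
  geo <- simulate_geography(7, seed = 4)
  truth <- sim_truth(sigma2_slope = 0.001, slope_cor = 0.5)
  rec <- simulate_children(geo, n_children = 800, n_preschools = 12,
                           truth = truth, seed = 5)
  led <- sim_truth_ledger(rec)
  expect_identical(led$params, truth)
  expect_equal(nrow(led$ward_effects), 7)
  expect_equal(nrow(led$preschool_effects), 12)
  expect_true(all(rec$ward_id %in% led$ward_effects$ward_id))
  expect_true(all(rec$preschool_id %in% led$preschool_effects$preschool_id))
  # slopes drawn with the requested spread
  expect_true(any(led$ward_effects$v1 != 0))
})

test_that("emitted item responses score back to the recorded totals", {
  geo <- simulate_geography(4, seed = 6)
  rec <- simulate_children(geo, n_children = 300, n_preschools = 8,
                           items = TRUE, seed = 7)
  scored <- score_sdq(dplyr::select(rec, dplyr::starts_with("item")))
  expect_equal(scored$total, rec$total_score)
})

test_that("records round-trip through CSV with ledger JSON alongside", {
  geo <- simulate_geography(4, seed = 8)
  rec <- simulate_children(geo, n_children = 200, n_preschools = 6, seed = 9)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_children_csv(rec, csv)
  write_truth_ledger(rec, js)
  back <- read_children_csv(csv)
  expect_equal(back$total_score, rec$total_score)
  expect_equal(back$sex, rec$sex)
  led <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(led$params$p_zero, 0.15)
  expect_equal(nrow(led$ward_effects), 4)
})
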