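test_that("the high-score threshold splits a ward-year at 15", {
  rec <- make_records(c(14L, 15L, 20L))
  agg <- aggregate_ward_year(rec)
  expect_equal(agg$Y, 2L)
  expect_equal(agg$E, 3L)
  expect_equal(agg$median_score, 15)
})

test_that("ward-year covariate proportions are group means", {
  rec <- make_records(rep(5L, 4), sex = c("male", "male", "female", "female"),
                      age_months = c(50, 60, 60, 70),
                      deprivation_quintile = c(1L, 1L, 1L, 5L))
  agg <- aggregate_ward_year(rec)
  expect_equal(agg$prop_boys, 0.5)
  expect_equal(agg$prop_most_deprived, 0.75)
  expect_equal(agg$prop_off_age, 0.5) # 50 and 70 months are outside 4.5-5.5y
})

test_that("aggregation matches a naive double loop on simulated data", {
  geo <- simulate_geography(8, seed = 4)
  rec <- simulate_children(geo, n_children = 3000, n_preschools = 25,
                           cohorts = 2010:2013, seed = 5)
  agg <- aggregate_ward_year(rec)
  # brute-force recomputation
  for (row in sample.int(nrow(agg), 10)) {
    w <- agg$ward_id[row]; co <- agg$cohort[row]
    sub <- rec[rec$ward_id == w & rec$cohort == co, ]
    expect_equal(agg$Y[row], sum(sub$total_score >= 15))
    expect_equal(agg$E[row], nrow(sub))
    expect_equal(agg$prop_boys[row], mean(sub$sex == "male"))
    expect_equal(agg$median_score[row], median(sub$total_score))
  }
  expect_equal(sum(agg$E), nrow(rec))
  expect_equal(sum(agg$Y), sum(rec$total_score >= 15))
  expect_error(aggregate_ward_year(dplyr::mutate(rec, ward_id = NA)),
               "unknown ward")
})

test_that("descriptive groups are exhaustive and percentages present at 1 d.p.", {
  geo <- simulate_geography(5, seed = 6)
  rec <- simulate_children(geo, n_children = 4000, n_preschools = 15, seed = 7)
  tab <- describe_sdq(rec, by = c("age_band", "sex", "deprivation", "cohort", "ward"))
  for (v in c("age_band", "sex", "deprivation", "cohort", "ward")) {
    expect_equal(sum(tab$N[tab$group_var == v]), nrow(rec))
  }
  overall <- tab[tab$group_var == "total", ]
  expect_equal(overall$N, nrow(rec))
  expect_equal(overall$pct_high, pct_high(sum(rec$total_score >= 15), nrow(rec)))
  expect_true(all(tab$pct_high == round_half_up(tab$pct_high, 1)))
  # markdown rendering carries one line per row plus a two-line header
  expect_length(describe_markdown(tab), nrow(tab) + 2)
})

test_that("constant scores give a zero-width IQR at the common value", {
  rec <- make_records(rep(7L, 25))
  tab <- describe_sdq(rec, by = "sex")
  expect_equal(tab$median, rep(7, 2))
  expect_equal(tab$q25, rep(7, 2))
  expect_equal(tab$q75, rep(7, 2))
})

test_that("nearest-rank quartiles reproduce integer IQRs", {
  x <- c(0L, 1L, 2L, 4L, 9L)
  q <- sdqmap:::quartiles_nearest_rank(x)
  expect_equal(unname(q), c(1, 4))
})
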