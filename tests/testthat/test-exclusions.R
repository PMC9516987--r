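test_that("an eligible five-year-old is retained and a 6.3-year-old is not", {
  rec <- make_records(c(5L, 5L), age_months = c(60, 6.3 * 12))
  kept <- apply_exclusions(rec)
  expect_equal(kept$child_id, 1L)
  tally <- exclusion_tally(kept)
  expect_equal(tally$n[tally$reason == "out_of_age"], 1L)
  expect_equal(tally$n[tally$reason == "total_excluded"], 1L)
})

test_that("empty input filters to empty output", {
  rec <- make_records(integer(0))
  kept <- apply_exclusions(rec)
  expect_equal(nrow(kept), 0L)
  expect_equal(exclusion_tally(kept)$n, rep(0L, 6))
})

test_that("overlap-adjusted accounting matches a whole-study-sized fixture", {
  # 41,128 records of which 5,957 fail at least one criterion (some fail
  # several), leaving 35,171 -- exclusion reasons must not double count
  n <- 41128L
  n_bad <- 5957L
  rec <- make_records(rep(5L, n))
  set.seed(11)
  bad <- sample.int(n, n_bad)
  grp <- split(bad, rep(1:5, length.out = n_bad))
  rec$in_study_area[grp[[1]]] <- FALSE
  rec$dob_known[grp[[2]]] <- FALSE
  rec$age_months[grp[[3]]] <- 80
  rec$postcode_valid[grp[[4]]] <- FALSE
  rec$total_score[grp[[5]]] <- NA
  # overlaps: the first 500 contaminated records also get a second defect
  rec$postcode_valid[bad[1:500]] <- FALSE
  kept <- apply_exclusions(rec)
  expect_equal(nrow(kept), 35171L)
  tally <- exclusion_tally(kept)
  expect_equal(tally$n[tally$reason == "total_excluded"], n_bad)
  expect_gt(sum(tally$n[tally$reason != "total_excluded"]), n_bad) # overlaps counted per reason
})

test_that("contamination injection flags a knowable subset", {
  geo <- simulate_geography(6, seed = 1)
  rec <- simulate_children(geo, n_children = 10000, n_preschools = 20, seed = 2)

  clean <- inject_exclusions(rec, rates = c(missing_dob = 0, missing_score = 0), seed = 3)
  expect_equal(clean$total_score, rec$total_score)
  expect_equal(attr(clean, "n_contaminated"), 0L)

  all_missing <- inject_exclusions(rec, rates = c(missing_score = 1), seed = 3)
  expect_equal(nrow(apply_exclusions(all_missing)), 0L)

  rates <- c(missing_dob = 0.02, invalid_postcode = 0.02, out_of_area = 0.01,
             out_of_age = 0.01, missing_score = 0.05)
  dirty <- inject_exclusions(rec, rates = rates, seed = 3)
  # independent union pass over the emitted flags
  union_bad <- !dirty$dob_known | !dirty$postcode_valid | !dirty$in_study_area |
    dirty$age_months < 48 | dirty$age_months > 72 | is.na(dirty$total_score)
  expect_equal(attr(dirty, "n_contaminated"), sum(union_bad))
  expect_equal(nrow(apply_exclusions(dirty)), nrow(rec) - sum(union_bad))
})
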