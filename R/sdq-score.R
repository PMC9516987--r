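#' Default SDQ item-to-domain configuration
#'
#' The Strengths and Difficulties Questionnaire has 25 items on a 0/1/2
#' Likert scale grouped into five domains of five items: emotional symptoms,
#' conduct problems, hyperactivity/inattention, peer problems, and prosocial
#' behaviour. Five items are positively worded and reverse-scored (a raw
#' response of 2 contributes 0). The mapping is configuration, not hard-coded,
#' so age-specific questionnaire variants that share the structure can reuse
#' one scoring engine.
#'
#' @return Tibble with columns `item` (1..25), `domain`, `reversed`.
#' @export
#' @examples
#' dplyr::count(sdq_item_map(), domain)
sdq_item_map <- function() {
  tibble::tibble(
    item = 1:25,
    domain = c("prosocial", "hyperactivity", "emotional", "prosocial", "conduct",
               "peer", "conduct", "emotional", "prosocial", "hyperactivity",
               "peer", "conduct", "emotional", "peer", "hyperactivity",
               "emotional", "prosocial", "conduct", "peer", "prosocial",
               "hyperactivity", "conduct", "peer", "emotional", "hyperactivity"),
    reversed = c(1:25) %in% c(7, 11, 14, 21, 25)
  )
}

difficulty_domains <- c("emotional", "conduct", "hyperactivity", "peer")

#' Score SDQ item responses
#'
#' Computes the five domain scores (each 0-10), the total difficulties score
#' (sum of the four difficulty domains, 0-40; prosocial excluded), the
#' four-band classification and the high-score flag from raw item responses.
#'
#' Banding for the total difficulties score: 0-10 close to average, 11-14
#' slightly raised, 15-17 high, 18-40 very high; `high` is `TRUE` for totals
#' of 15 or more, the threshold indicating a high risk of psychopathology.
#'
#' Partially completed forms are prorated per standard SDQ practice: a domain
#' score is `round(mean of answered items * 5)` when at least 3 of its 5 items
#' are answered, otherwise the domain — and hence the total — is missing.
#'
#' @param items Data frame or matrix of raw responses, one row per child and
#'   25 item columns in questionnaire order; values 0, 1, 2 or `NA`.
#' @param item_map Item configuration as from [sdq_item_map()].
#' @return Tibble with one row per child: the five domain scores, `total`,
#'   `band` (ordered factor), `high`, and `prorated` (any domain prorated).
#' @export
#' @examples
#' zero_form <- matrix(0, 1, 25)
#' zero_form[c(7, 11, 14, 21, 25)] <- 2 # positive response on reversed items
#' score_sdq(zero_form)$total
score_sdq <- function(items, item_map = sdq_item_map()) {
  m <- as.matrix(items)
  if (ncol(m) != nrow(item_map)) {
    abort(sprintf("`items` must have %d columns (one per item), got %d.",
                  nrow(item_map), ncol(m)))
  }
  storage.mode(m) <- "double"
  bad <- which(!is.na(m) & !(m %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Item %d (row %d) has invalid response %s; items must be 0, 1, 2 or NA.",
                  bad[1, "col"], bad[1, "row"], m[bad[1, , drop = FALSE]]))
  }
  scored <- m
  rev_idx <- which(item_map$reversed)
  scored[, rev_idx] <- 2 - scored[, rev_idx]

  domains <- unique(item_map$domain)
  dom_scores <- matrix(NA_real_, nrow(m), length(domains),
                       dimnames = list(NULL, domains))
  prorated <- logical(nrow(m))
  for (d in domains) {
    cols <- item_map$item[item_map$domain == d]
    sub <- scored[, cols, drop = FALSE]
    n_ans <- rowSums(!is.na(sub))
    s <- rowSums(sub, na.rm = TRUE)
    full <- n_ans == length(cols)
    partial <- n_ans >= 3 & !full
    dom_scores[full, d] <- s[full]
    dom_scores[partial, d] <- round_half_up(s[partial] / n_ans[partial] * length(cols))
    prorated <- prorated | partial
  }
  total <- rowSums(dom_scores[, difficulty_domains, drop = FALSE])
  tibble::tibble(
    emotional = unname(dom_scores[, "emotional"]),
    conduct = unname(dom_scores[, "conduct"]),
    hyperactivity = unname(dom_scores[, "hyperactivity"]),
    peer = unname(dom_scores[, "peer"]),
    prosocial = unname(dom_scores[, "prosocial"]),
    total = as.integer(unname(total)),
    band = sdq_band(total),
    high = total >= 15,
    prorated = prorated
  )
}

#' Band a total difficulties score
#'
#' @param total Integer vector of total difficulties scores (0-40).
#' @return Ordered factor with levels `close_to_average` (0-10),
#'   `slightly_raised` (11-14), `high` (15-17), `very_high` (18-40).
#' @export
sdq_band <- function(total) {
  if (any(total < 0 | total > 40, na.rm = TRUE)) {
    abort("Total difficulties scores must lie in [0, 40].")
  }
  cut(total, breaks = c(-0.5, 10.5, 14.5, 17.5, 40.5),
      labels = c("close_to_average", "slightly_raised", "high", "very_high"),
      ordered_result = TRUE)
}

#' Percentage of high scorers, presentation-rounded
#'
#' The descriptive-table percentage: `100 * n_high / n`, rounded half-up to
#' one decimal place.
#'
#' @param n_high Count of children with total score >= 15.
#' @param n Group size.
#' @return Numeric percentage at 1 decimal place.
#' @export
#' @examples
#' pct_high(3149, 35171) # 9.0
pct_high <- function(n_high, n) {
  round_half_up(100 * n_high / n, 1)
}

#' Apply the study exclusion criteria
#'
#' Children are excluded when they live outside the study area, are missing a
#' date of birth, are under 4 or over 6 years old at primary school entry,
#' have a missing or invalid postcode, or are missing a total difficulties
#' score. A child failing several criteria is excluded once; the tally counts
#' every reason plus the overlap-adjusted total.
#'
#' @param records Tibble of child records carrying `in_study_area`,
#'   `dob_known`, `postcode_valid` (logicals), `age_months`, `total_score`.
#' @return The retained records, with the exclusion tally available via
#'   [exclusion_tally()].
#' @export
apply_exclusions <- function(records) {
  needed <- c("in_study_area", "dob_known", "postcode_valid", "age_months",
              "total_score")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(sprintf("`records` is missing eligibility columns: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  fails <- exclusion_flags(records)
  any_fail <- Reduce(`|`, fails)
  tally <- tibble::tibble(
    reason = c(names(fails), "total_excluded"),
    n = unname(c(vapply(fails, sum, integer(1)), sum(any_fail)))
  )
  out <- dplyr::filter(records, !any_fail)
  attr(out, "exclusion_tally") <- tally
  out
}

exclusion_flags <- function(records) {
  list(
    out_of_area = !records$in_study_area,
    missing_dob = !records$dob_known,
    out_of_age = records$dob_known &
      (records$age_months < 48 | records$age_months > 72),
    invalid_postcode = !records$postcode_valid,
    missing_score = is.na(records$total_score)
  )
}

#' @rdname apply_exclusions
#' @param retained Output of [apply_exclusions()].
#' @return `exclusion_tally()`: tibble of per-reason counts and the
#'   overlap-adjusted `total_excluded`.
#' @export
exclusion_tally <- function(retained) {
  t <- attr(retained, "exclusion_tally")
  if (is.null(t)) abort("No exclusion tally attached; run `apply_exclusions()` first.")
  t
}

#' Aggregate child records to ward-by-cohort counts
#'
#' Produces the disease-mapping input: for each ward and cohort year, the
#' count of high scorers `Y`, the number of assessed children `E` (the
#' exposure/offset), ward covariates (proportion of boys, proportion in the
#' most deprived quintile, proportion outside the expected school-start age
#' of 4.5-5.5 years), and the median total score (for the sensitivity
#' variant modelling ward medians).
#'
#' @param records Scored, filtered child records with `ward_id`, `cohort`,
#'   `total_score`, `sex`, `deprivation_quintile`, `age_months`.
#' @return Tibble with one row per observed ward x cohort.
#' @export
aggregate_ward_year <- function(records) {
  if (any(is.na(records$ward_id))) {
    abort("Records with unknown ward cannot be aggregated.")
  }
  records |>
    dplyr::group_by(.data$ward_id, .data$cohort) |>
    dplyr::summarise(
      Y = sum(.data$total_score >= 15),
      E = dplyr::n(),
      prop_boys = mean(.data$sex == "male"),
      prop_most_deprived = mean(.data$deprivation_quintile == 1),
      prop_off_age = mean(.data$age_months < 54 | .data$age_months > 66),
      median_score = median(.data$total_score),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$ward_id, .data$cohort)
}

#' Age band at school start
#'
#' Half-open bands partitioning the eligible 4-6 year range:
#' `[4,4.5)`, `[4.5,5)`, `[5,5.5)`, `[5.5,6]` years.
#'
#' @param age_months Age in months at planned primary school entry.
#' @return Ordered factor of band labels.
#' @export
age_band <- function(age_months) {
  cut(age_months / 12, breaks = c(4, 4.5, 5, 5.5, 6),
      labels = c("4-4.5", "4.5-5", "5-5.5", "5.5-6"),
      right = FALSE, include.lowest = FALSE, ordered_result = TRUE) |>
    (\(b) { b[age_months == 72] <- "5.5-6"; b })()
}

#' Descriptive table of scores and high-score proportions
#'
#' Per-group sample size, high-score count and percentage (1 decimal place,
#' half-up), median total score and nearest-rank 25th/75th percentiles —
#' the structure of a baseline characteristics table.
#'
#' @param records Scored, filtered child records.
#' @param by Character vector of grouping variables from `age_band`, `sex`,
#'   `deprivation`, `cohort`, `ward`; `"total"` gives the one-row overall
#'   summary and is always included first.
#' @return Tibble with columns `group_var`, `level`, `N`, `n_high`,
#'   `pct_high`, `median`, `q25`, `q75`.
#' @export
describe_sdq <- function(records, by = c("sex", "cohort")) {
  allowed <- c("age_band", "sex", "deprivation", "cohort", "ward")
  bad <- setdiff(by, allowed)
  if (length(bad)) {
    abort(sprintf("Unknown grouping variable(s): %s.", paste(bad, collapse = ", ")))
  }
  df <- dplyr::mutate(
    records,
    age_band = age_band(.data$age_months),
    deprivation = .data$deprivation_quintile,
    ward = .data$ward_id
  )
  one_group <- function(var) {
    keys <- if (var == "total") rep("total", nrow(df)) else as.character(df[[var]])
    df |>
      dplyr::mutate(.level = keys) |>
      dplyr::group_by(.data$.level) |>
      dplyr::summarise(
        N = dplyr::n(),
        n_high = sum(.data$total_score >= 15),
        pct_high = pct_high(n_high, N),
        median = median(.data$total_score),
        q25 = quartiles_nearest_rank(.data$total_score)[["q25"]],
        q75 = quartiles_nearest_rank(.data$total_score)[["q75"]],
        .groups = "drop"
      ) |>
      dplyr::mutate(group_var = var, .before = 1) |>
      dplyr::rename(level = ".level")
  }
  purrr::map_dfr(c("total", by), one_group)
}

#' Emit a descriptive table as Markdown
#'
#' @param tab Output of [describe_sdq()].
#' @return Character vector of Markdown lines.
#' @export
describe_markdown <- function(tab) {
  hdr <- c("| Group | Level | N | High score (%) | Median (IQR) |",
           "|---|---|---:|---:|---|")
  rows <- purrr::pmap_chr(tab, function(group_var, level, N, n_high, pct_high,
                                        median, q25, q75) {
    sprintf("| %s | %s | %d | %d (%.1f%%) | %g (%g-%g) |",
            group_var, level, N, n_high, pct_high, median, q25, q75)
  })
  c(hdr, rows)
}
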