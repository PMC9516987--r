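#' Ground-truth parameters for the synthetic-data generator
#'
#' The generative model for a child's total difficulties score is the same
#' zero-inflated negative binomial multilevel model the package fits:
#' \deqn{Y_{ijk} \sim \mathrm{ZINB}(\lambda_{ijk}, p, r), \quad
#'  \log\lambda_{ijk} = \beta_0 + (\beta_1 + v_{1j})t + \alpha_k + v_{0j}
#'   + \beta_{male}\,male_i + \beta_{age^2}(age_i-59)^2 + \beta_{dep[q_i]}}
#' with ward intercepts \eqn{v_{0j} \sim N(0,\sigma^2_{ward})}, preschool
#' effects \eqn{\alpha_k \sim N(0,\sigma^2_{preschool})} and optional
#' differential ward slopes \eqn{v_{1j}}.
#'
#' Defaults are chosen so the default simulation resembles a city-wide
#' preschool SDQ collection: intercept rate 4.079 for the reference child
#' (girl, least-deprived quintile, age 59 months, first cohort), boys scoring
#' 37% higher, a small positive cohort trend (RR 1.008/year), a deprivation
#' gradient rising to RR 1.243 for the most deprived quintile, preschool
#' variance 0.062 exceeding ward variance 0.013, and zero-inflation/
#' overdispersion (p = 0.15, r = 2) giving a right-skewed score distribution
#' with median about 4 and roughly 9% of children scoring 15 or more.
#'
#' @param beta0 Log-scale intercept.
#' @param beta_cohort Log-RR per cohort step.
#' @param beta_male Log-RR for boys vs girls.
#' @param beta_age_sq Log-RR per squared month of age deviation from 59.
#' @param beta_dep Length-4 log-RR contrasts for deprivation quintiles
#'   4, 3, 2, 1 versus the least-deprived quintile 5.
#' @param sigma2_ward,sigma2_preschool,sigma2_slope Variances of ward
#'   intercepts, preschool effects and differential slopes (0 disables
#'   slopes).
#' @param slope_cor Correlation between ward intercepts and slopes, in
#'   `[-1, 1]`.
#' @param p_zero Zero-inflation proportion in `[0, 1)`.
#' @param r_overdisp Positive overdispersion parameter.
#' @return A `sim_truth` list of the validated parameters.
#' @export
sim_truth <- function(beta0 = log(4.079),
                      beta_cohort = log(1.008),
                      beta_male = log(1.370),
                      beta_age_sq = log(1.003),
                      beta_dep = log(c(1.115, 1.174, 1.234, 1.243)),
                      sigma2_ward = 0.013,
                      sigma2_preschool = 0.062,
                      sigma2_slope = 0,
                      slope_cor = 0,
                      p_zero = 0.15,
                      r_overdisp = 2.0) {
  if (length(beta_dep) != 4) abort("`beta_dep` must have length 4 (quintiles 4,3,2,1 vs 5).")
  if (sigma2_ward < 0 || sigma2_preschool < 0 || sigma2_slope < 0) {
    abort("Variance components must be non-negative.")
  }
  if (abs(slope_cor) > 1) abort("`slope_cor` must lie in [-1, 1].")
  if (p_zero < 0 || p_zero >= 1) abort("`p_zero` must lie in [0, 1).")
  if (r_overdisp <= 0) abort("`r_overdisp` must be positive.")
  structure(list(beta0 = beta0, beta_cohort = beta_cohort,
                 beta_male = beta_male, beta_age_sq = beta_age_sq,
                 beta_dep = beta_dep, sigma2_ward = sigma2_ward,
                 sigma2_preschool = sigma2_preschool,
                 sigma2_slope = sigma2_slope, slope_cor = slope_cor,
                 p_zero = p_zero, r_overdisp = r_overdisp),
            class = "sim_truth")
}

# marginal age-band and deprivation-quintile mixtures for the default
# population (proportions of assessed children per band / quintile 1..5)
default_age_band_weights <- c(0.060, 0.468, 0.435, 0.037)
default_dep_marginal <- c(0.273, 0.233, 0.190, 0.160, 0.144)

#' Assign preschools to home wards
#'
#' Each preschool has one home ward (drawn with ward population weights);
#' children mostly attend a preschool in their own ward, with a small
#' probability of attending one in an adjacent ward, so preschool and ward
#' are cross-classified rather than nested.
#'
#' @param geo A `ward_geography`.
#' @param n_preschools Number of preschools.
#' @param seed Integer seed.
#' @return Tibble `preschool_id`, `home_ward`.
#' @export
simulate_preschools <- function(geo, n_preschools = 180, seed = NULL) {
  with_seed(seed, {
    home <- sample(geo$wards$ward_id, n_preschools, replace = TRUE,
                   prob = geo$wards$pop_weight)
    tibble::tibble(preschool_id = seq_len(n_preschools), home_ward = home)
  })
}

#' Simulate child-level SDQ records with known ground truth
#'
#' Generates one row per assessed child: ward and preschool membership,
#' cohort, sex, age at school start, within-city deprivation quintile and a
#' total difficulties score drawn from the zero-inflated negative binomial
#' multilevel model described in [sim_truth()]. Scores above the SDQ maximum
#' of 40 are rejected and redrawn, preserving the model family on the
#' observed support. Every random effect drawn is recorded in a ground-truth
#' ledger (see [sim_truth_ledger()]) for parameter-recovery testing.
#'
#' @param geo A `ward_geography` from [simulate_geography()].
#' @param n_children Number of children (default 35,000, a whole-city
#'   eight-cohort collection).
#' @param n_preschools Number of preschools (default 180).
#' @param cohorts Ordered vector of cohort years.
#' @param prob_male Probability a child is male.
#' @param age_band_weights Mixture weights over the four school-start age
#'   bands 4-4.5, 4.5-5, 5-5.5, 5.5-6 years; ages are drawn uniformly in
#'   months within the band.
#' @param deprivation_mixing Optional `n_wards x 5` matrix of per-ward
#'   quintile probabilities (rows sum to 1). Default: ward-varying Dirichlet
#'   draws centred on the city-wide marginal, concentration 10.
#' @param adjacent_prob Probability a child attends a preschool in a ward
#'   adjacent to their own.
#' @param truth A [sim_truth()] parameter set.
#' @param items If `TRUE`, also emit 25 raw item responses per child
#'   consistent with the drawn total.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return Tibble of child records with the truth ledger attached as an
#'   attribute.
#' @export
simulate_children <- function(geo,
                              n_children = 35000,
                              n_preschools = 180,
                              cohorts = 2010:2017,
                              prob_male = 0.51,
                              age_band_weights = default_age_band_weights,
                              deprivation_mixing = NULL,
                              adjacent_prob = 0.1,
                              truth = sim_truth(),
                              items = FALSE,
                              seed = NULL) {
  if (n_preschools > n_children) abort("`n_preschools` must not exceed `n_children`.")
  if (abs(sum(age_band_weights) - 1) > 1e-8) {
    abort("`age_band_weights` must sum to 1.")
  }
  n_wards <- nrow(geo$wards)
  with_seed(seed, {
    if (is.null(deprivation_mixing)) {
      deprivation_mixing <- t(vapply(seq_len(n_wards), function(j) {
        g <- rgamma(5, shape = 10 * default_dep_marginal)
        g / sum(g)
      }, numeric(5)))
    }
    if (!all(dim(deprivation_mixing) == c(n_wards, 5)) ||
        any(abs(rowSums(deprivation_mixing) - 1) > 1e-8)) {
      abort("`deprivation_mixing` must be n_wards x 5 with rows summing to 1.")
    }

    preschools <- tibble::tibble(
      preschool_id = seq_len(n_preschools),
      home_ward = sample(geo$wards$ward_id, n_preschools, replace = TRUE,
                         prob = geo$wards$pop_weight)
    )

    # random effects (the ground truth ledger)
    v0 <- rnorm(n_wards, 0, sqrt(truth$sigma2_ward))
    if (truth$sigma2_slope > 0) {
      # bivariate normal intercept/slope pairs via conditional draw
      s0 <- sqrt(truth$sigma2_ward)
      s1 <- sqrt(truth$sigma2_slope)
      cond_mean <- if (s0 > 0) truth$slope_cor * s1 / s0 * v0 else rep(0, n_wards)
      cond_sd <- s1 * sqrt(1 - truth$slope_cor^2)
      v1 <- rnorm(n_wards, cond_mean, cond_sd)
    } else {
      v1 <- rep(0, n_wards)
    }
    alpha <- rnorm(n_preschools, 0, sqrt(truth$sigma2_preschool))

    ward <- sample(geo$wards$ward_id, n_children, replace = TRUE,
                   prob = geo$wards$pop_weight)
    cohort <- sample(cohorts, n_children, replace = TRUE)
    t_step <- cohort - min(cohorts)
    male <- rbinom(n_children, 1, prob_male)
    band <- sample.int(4, n_children, replace = TRUE, prob = age_band_weights)
    band_lo <- c(48, 54, 60, 66)[band]
    age_months <- runif(n_children, band_lo, band_lo + 6)
    dep <- vapply(ward, function(j) {
      sample.int(5, 1, prob = deprivation_mixing[j, ])
    }, integer(1))

    preschool <- assign_preschools(ward, preschools, geo$adjacency, adjacent_prob)

    dep_mult <- c(rev(truth$beta_dep), 0) # quintile 1..5 log-RR (5 = reference)
    log_lambda <- truth$beta0 +
      (truth$beta_cohort + v1[ward]) * t_step +
      alpha[preschool] + v0[ward] +
      truth$beta_male * male +
      truth$beta_age_sq * (age_months - 59)^2 +
      dep_mult[dep]
    lambda <- exp(log_lambda)

    p_over <- mean((1 - truth$p_zero) *
      stats::pnbinom(40, size = truth$r_overdisp, mu = lambda, lower.tail = FALSE))
    if (p_over > 0.01) {
      warn(sprintf(paste("ZINB means imply average Pr(score > 40) = %.3f;",
                         "truncation materially distorts the generative model."),
           p_over))
    }
    score <- rzinb_truncated(lambda, truth$p_zero, truth$r_overdisp, upper = 40L)

    out <- tibble::tibble(
      child_id = seq_len(n_children),
      preschool_id = preschool,
      ward_id = ward,
      cohort = cohort,
      sex = ifelse(male == 1, "male", "female"),
      age_months = age_months,
      deprivation_quintile = dep,
      total_score = score,
      postcode_valid = TRUE,
      in_study_area = TRUE,
      dob_known = TRUE
    )
    if (items) {
      im <- items_from_totals(score, seed = NULL) # RNG already seeded
      out <- dplyr::bind_cols(out, im)
    }
    attr(out, "truth_ledger") <- list(
      params = truth,
      ward_effects = tibble::tibble(ward_id = geo$wards$ward_id, v0 = v0, v1 = v1),
      preschool_effects = tibble::tibble(preschool_id = preschools$preschool_id,
                                         home_ward = preschools$home_ward,
                                         alpha = alpha)
    )
    out
  })
}

# draw ZINB rejected-and-redrawn onto the support 0..upper
rzinb_truncated <- function(lambda, p, r, upper = 40L) {
  n <- length(lambda)
  structural <- rbinom(n, 1L, p) == 1L
  y <- rnbinom(n, size = r, mu = lambda)
  y[structural] <- 0L
  redo <- which(y > upper)
  while (length(redo)) {
    y[redo] <- rnbinom(length(redo), size = r, mu = lambda[redo])
    redo <- redo[y[redo] > upper]
  }
  y
}

# children attend a preschool in their own ward, or with probability
# `adjacent_prob` one in an adjacent ward (cross-classification)
assign_preschools <- function(ward, preschools, W, adjacent_prob) {
  by_ward <- split(preschools$preschool_id, preschools$home_ward)
  ids <- as.character(seq_len(nrow(W)))
  use_adjacent <- runif(length(ward)) < adjacent_prob
  vapply(seq_along(ward), function(i) {
    j <- ward[i]
    pool <- NULL
    if (use_adjacent[i]) {
      nb <- which(W[j, ] > 0)
      pool <- unlist(by_ward[as.character(nb)], use.names = FALSE)
    }
    if (is.null(pool) || length(pool) == 0L) {
      pool <- by_ward[[as.character(j)]]
    }
    if (is.null(pool) || length(pool) == 0L) {
      nb <- which(W[j, ] > 0)
      pool <- unlist(by_ward[as.character(nb)], use.names = FALSE)
    }
    if (is.null(pool) || length(pool) == 0L) pool <- preschools$preschool_id
    pool[sample.int(length(pool), 1L)]
  }, integer(1))
}

# raw item responses consistent with given difficulty totals: distribute the
# total over the 40 unit slots of the 20 difficulty items (2 per item), then
# un-reverse the reverse-scored items; prosocial items are iid 0/1/2
items_from_totals <- function(total, item_map = sdq_item_map(), seed = NULL) {
  diff_items <- item_map$item[item_map$domain != "prosocial"]
  pro_items <- item_map$item[item_map$domain == "prosocial"]
  n <- length(total)
  scored <- matrix(0, n, 25)
  slots <- rep(diff_items, each = 2)
  for (i in seq_len(n)) {
    if (total[i] > 0) {
      take <- sample(slots, total[i])
      tab <- table(take)
      scored[i, as.integer(names(tab))] <- as.integer(tab)
    }
  }
  scored[, pro_items] <- sample(0:2, n * length(pro_items), replace = TRUE)
  raw <- scored
  rev_idx <- item_map$item[item_map$reversed]
  raw[, rev_idx] <- 2 - raw[, rev_idx]
  colnames(raw) <- sprintf("item%02d", 1:25)
  tibble::as_tibble(raw)
}

#' Retrieve the ground-truth ledger of a simulated data set
#'
#' @param records Output of [simulate_children()].
#' @return List with `params` (the [sim_truth()] used), `ward_effects`
#'   (tibble `ward_id`, `v0`, `v1`) and `preschool_effects` (tibble
#'   `preschool_id`, `home_ward`, `alpha`).
#' @export
sim_truth_ledger <- function(records) {
  l <- attr(records, "truth_ledger")
  if (is.null(l)) abort("No truth ledger attached; not a simulated data set?")
  l
}

#' Contaminate simulated records with exclusion-triggering defects
#'
#' Randomly marks records as missing date of birth, having an invalid
#' postcode, living outside the study area, being outside the eligible 4-6
#' year age range, or missing a total score, at the given rates. Used to
#' exercise the exclusion filter on data with a knowable contaminated subset.
#'
#' @param records Child records.
#' @param rates Named numeric vector of contamination rates in `[0, 1]` with
#'   names among `missing_dob`, `invalid_postcode`, `out_of_area`,
#'   `out_of_age`, `missing_score`.
#' @param seed Integer seed.
#' @return Records with flags set; the number of contaminated records (one
#'   or more defects) is attached as attribute `n_contaminated`.
#' @export
inject_exclusions <- function(records,
                              rates = c(missing_dob = 0.02,
                                        invalid_postcode = 0.02,
                                        out_of_area = 0.01,
                                        out_of_age = 0.01,
                                        missing_score = 0.05),
                              seed = NULL) {
  allowed <- c("missing_dob", "invalid_postcode", "out_of_area",
               "out_of_age", "missing_score")
  if (is.null(names(rates)) || !all(names(rates) %in% allowed)) {
    abort(sprintf("`rates` must be named among: %s.", paste(allowed, collapse = ", ")))
  }
  if (any(rates < 0 | rates > 1)) abort("`rates` must lie in [0, 1].")
  n <- nrow(records)
  ledger <- attr(records, "truth_ledger")
  with_seed(seed, {
    hit <- function(rate) if (is.na(rate)) rep(FALSE, n) else runif(n) < rate
    h_dob <- hit(rates["missing_dob"])
    h_pc <- hit(rates["invalid_postcode"])
    h_area <- hit(rates["out_of_area"])
    h_age <- hit(rates["out_of_age"])
    h_score <- hit(rates["missing_score"])
    records$dob_known[h_dob] <- FALSE
    records$postcode_valid[h_pc] <- FALSE
    records$in_study_area[h_area] <- FALSE
    if (any(h_age)) {
      low <- runif(sum(h_age)) < 0.5
      records$age_months[h_age] <- ifelse(low, runif(sum(h_age), 40, 47.9),
                                          runif(sum(h_age), 72.1, 80))
    }
    records$total_score[h_score] <- NA_integer_
    attr(records, "n_contaminated") <- sum(h_dob | h_pc | h_area | h_age | h_score)
    attr(records, "truth_ledger") <- ledger
    records
  })
}

#' Write / read child records as CSV
#'
#' The documented header is the column set of [simulate_children()]; the
#' truth ledger (when present) can be written alongside as JSON with
#' [write_truth_ledger()].
#'
#' @param records Child records tibble.
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_children_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_children_csv
#' @export
read_children_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "")
  tibble::as_tibble(df)
}

#' @rdname write_children_csv
#' @export
write_truth_ledger <- function(records, path) {
  l <- sim_truth_ledger(records)
  jsonlite::write_json(
    list(params = unclass(l$params),
         ward_effects = l$ward_effects,
         preschool_effects = l$preschool_effects),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
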