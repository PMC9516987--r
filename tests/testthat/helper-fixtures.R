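# shared fixture builders; everything is generated in code at test time

# adjacency of a path graph 1-2-...-n
path_adjacency <- function(n) {
  W <- matrix(0L, n, n)
  if (n > 1) W[cbind(1:(n - 1), 2:n)] <- 1L
  W + t(W)
}

# a 25-item raw response row achieving a given difficulty total:
# zero-contribution baseline (raw 0, or raw 2 on reversed items), then fill
# difficulty items in questionnaire order with up to 2 points each
make_item_row <- function(total) {
  map <- sdq_item_map()
  raw <- ifelse(map$reversed, 2, 0)
  remaining <- total
  for (it in map$item[map$domain != "prosocial"]) {
    if (remaining <= 0) break
    pts <- min(2, remaining)
    raw[it] <- if (map$reversed[it]) 2 - pts else pts
    remaining <- remaining - pts
  }
  matrix(raw, nrow = 1)
}

# minimal eligible child record set
make_records <- function(total_score,
                         ward_id = 1L, cohort = 2010L, sex = "female",
                         age_months = 60, deprivation_quintile = 5L,
                         preschool_id = 1L) {
  n <- length(total_score)
  tibble::tibble(
    child_id = seq_len(n),
    preschool_id = rep_len(preschool_id, n),
    ward_id = rep_len(ward_id, n),
    cohort = rep_len(cohort, n),
    sex = rep_len(sex, n),
    age_months = rep_len(age_months, n),
    deprivation_quintile = rep_len(deprivation_quintile, n),
    total_score = total_score,
    postcode_valid = TRUE, in_study_area = TRUE, dob_known = TRUE
  )
}

# ward-year counts simulated directly from the Poisson disease-mapping
# model: log theta_jt = b0 + b1 * t + u0_j, known truth returned alongside
make_dm_counts <- function(n_wards = 21, n_cohorts = 8, E_mean = 200,
                           b0 = log(0.08), b1 = 0, sigma2_u0 = 0.02,
                           seed = 1) {
  set.seed(seed)
  u0 <- rnorm(n_wards, 0, sqrt(sigma2_u0))
  grid <- expand.grid(ward_id = seq_len(n_wards), cohort = 2010 + seq_len(n_cohorts) - 1)
  t <- grid$cohort - 2010
  E <- rpois(nrow(grid), E_mean) + 1L
  theta <- exp(b0 + b1 * t + u0[grid$ward_id])
  Y <- rpois(nrow(grid), E * theta)
  Y <- pmin(Y, E)
  tibble::tibble(ward_id = grid$ward_id, cohort = grid$cohort, Y = Y, E = E,
                 median_score = 4, u0_true = u0[grid$ward_id])
}

# independent ZINB log-pmf via explicit log-gamma algebra (test oracle; the
# package's dzinb goes through dnbinom instead)
zinb_logpmf_oracle <- function(y, lambda, p, r) {
  lnb <- lgamma(y + r) - lgamma(r) - lfactorial(y) +
    r * (log(r) - log(r + lambda)) + y * (log(lambda) - log(r + lambda))
  ifelse(y == 0, log(p + (1 - p) * exp(lnb)), log1p(-p) + lnb)
}

# brute-force O(n^2) Moran's I (test oracle)
moran_bruteforce <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}
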