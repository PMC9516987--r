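#' Moran's I spatial autocorrelation statistic
#'
#' Global autocorrelation of a ward-level variable under a binary (queen
#' contiguity) weight matrix:
#' \deqn{I = \frac{n}{S_0}\,
#'  \frac{\sum_i\sum_j w_{ij} z_i z_j}{\sum_i z_i^2}, \qquad z_i = x_i-\bar x,
#'  \; S_0 = \sum_i\sum_j w_{ij}.}
#' Values near 1 indicate similar neighbours, near -1 dissimilar neighbours,
#' near the permutation expectation \eqn{-1/(n-1)} no spatial association.
#' Binary weights are used as-is by default; pass `row_standardize = TRUE`
#' to normalise rows to sum to one first.
#'
#' @param values Numeric vector over wards (not all equal).
#' @param W Square symmetric non-negative weight matrix, zero diagonal,
#'   ordered as `values`.
#' @param row_standardize Normalise rows of `W` before computing?
#' @return The statistic (numeric scalar).
#' @export
#' @examples
#' W <- matrix(0, 4, 4); W[cbind(1:3, 2:4)] <- 1; W <- W + t(W) # path graph
#' moran_i(c(1, 2, 3, 4), W) # 1/3
moran_i <- function(values, W, row_standardize = FALSE) {
  n <- length(values)
  if (n < 2) abort("Moran's I needs at least 2 areas.")
  if (!all(dim(W) == c(n, n))) abort("`W` must be n x n matching `values`.")
  if (any(diag(W) != 0)) abort("`W` must have a zero diagonal.")
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) abort("`values` are constant; Moran's I is undefined.")
  if (row_standardize) {
    rs <- rowSums(W)
    W <- W / ifelse(rs > 0, rs, 1)
  }
  S0 <- sum(W)
  as.numeric(n / S0 * (t(z) %*% W %*% z) / denom)
}

#' Permutation test for Moran's I
#'
#' Tests the null of no spatial autocorrelation (I equal to its permutation
#' expectation \eqn{-1/(n-1)}) by randomly relabelling the areas. With only
#' a few dozen areas a permutation reference distribution is preferred over
#' the normal approximation. The two-sided p-value is
#' \eqn{(1 + \#\{|I_{perm} - E[I]| \ge |I_{obs} - E[I]|\}) / (B + 1)}.
#'
#' @inheritParams moran_i
#' @param n_permutations Number of permutations (>= 99).
#' @param seed Integer seed for reproducible permutations.
#' @param alternative `"two.sided"` (default) or `"greater"` (positive
#'   autocorrelation only).
#' @return A `moran_result` tibble row: `I`, `expected_I`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
moran_test <- function(values, W, n_permutations = 999, seed = NULL,
                       row_standardize = FALSE,
                       alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (n_permutations < 99) abort("Use at least 99 permutations.")
  n <- length(values)
  if (n < 3) abort("The permutation test needs at least 3 areas.")
  I_obs <- moran_i(values, W, row_standardize)
  E_I <- -1 / (n - 1)
  with_seed(seed, {
    I_perm <- vapply(seq_len(n_permutations), function(b) {
      moran_i(values[sample.int(n)], W, row_standardize)
    }, numeric(1))
    extreme <- switch(alternative,
      two.sided = abs(I_perm - E_I) >= abs(I_obs - E_I) - 1e-12,
      greater = I_perm >= I_obs - 1e-12
    )
    tibble::tibble(
      I = I_obs,
      expected_I = E_I,
      p_value = (1 + sum(extreme)) / (n_permutations + 1),
      n_permutations = n_permutations,
      seed = seed %||% NA_integer_
    )
  })
}

#' Randomized PIT residuals from posterior-predictive simulations
#'
#' Scaled (probability integral transform) residuals for discrete outcomes:
#' each observation is ranked among `n_sim` replicates simulated from the
#' fitted model, with ties broken by a uniform draw inside the tie interval.
#' Under a correctly specified model the residuals are marginally
#' Uniform(0, 1); values near 0 (1) flag observations smaller (larger) than
#' the model expects.
#'
#' @param observed Numeric vector of observed outcomes (length n).
#' @param simulated n x n_sim matrix of replicates, row i simulated from the
#'   model for observation i.
#' @param seed Integer seed for the tie-breaking uniforms.
#' @return Numeric vector of residuals in (0, 1).
#' @export
pit_residuals <- function(observed, simulated, seed = NULL) {
  n <- length(observed)
  if (nrow(simulated) != n) abort("`simulated` must have one row per observation.")
  n_sim <- ncol(simulated)
  with_seed(seed, {
    below <- rowSums(simulated < observed)
    ties <- rowSums(simulated == observed)
    u <- runif(n)
    (below + u * (ties + 1)) / (n_sim + 1)
  })
}

#' Moran screen of ward-aggregated residuals
#'
#' Averages per-observation scaled residuals within wards and applies the
#' Moran permutation test. A non-significant result supports modelling the
#' ward effects as unstructured (exchangeable) heterogeneity; a significant
#' one suggests a spatially structured prior instead. The decision is
#' returned alongside the test.
#'
#' @param residuals Per-observation residuals (e.g. from [pit_residuals()]).
#' @param ward_ids Ward membership of each observation, matching the row
#'   order of `W`'s dimnames (integer ids 1..n).
#' @param W Adjacency matrix over wards.
#' @param alpha Significance threshold for the structure decision.
#' @inheritParams moran_test
#' @return A `moran_result` row with an added `spatial_structure` column
#'   (`"structured"` or `"unstructured"`) and the per-ward means as
#'   attribute `ward_means`.
#' @export
residual_moran_screen <- function(residuals, ward_ids, W,
                                  n_permutations = 999, seed = NULL,
                                  alpha = 0.05) {
  if (length(residuals) != length(ward_ids)) {
    abort("`residuals` and `ward_ids` must have the same length.")
  }
  n_wards <- nrow(W)
  if (!all(ward_ids %in% seq_len(n_wards))) {
    abort("Every `ward_id` must index a row of `W`.")
  }
  means <- vapply(seq_len(n_wards), function(j) mean(residuals[ward_ids == j]),
                  numeric(1))
  if (anyNA(means)) abort("Every ward must have at least one residual.")
  res <- moran_test(means, W, n_permutations = n_permutations, seed = seed)
  res$spatial_structure <- ifelse(res$p_value <= alpha, "structured", "unstructured")
  attr(res, "ward_means") <- means
  res
}

#' Deviance Information Criterion from posterior draws
#'
#' \eqn{DIC = \bar D + p_D} with effective parameter count
#' \eqn{p_D = \bar D - D(\bar\theta)}, where \eqn{D(\theta) = -2\log
#' L(\theta)}, \eqn{\bar D} is the posterior mean deviance and
#' \eqn{D(\bar\theta)} the deviance at the posterior mean. Lower values
#' indicate better fit among comparable models.
#'
#' @param deviance_draws Vector of deviance values, one per posterior draw.
#' @param deviance_at_mean Deviance evaluated at the posterior means.
#' @return Tibble row: `D_bar`, `D_at_mean`, `p_D`, `DIC`.
#' @export
compute_dic <- function(deviance_draws, deviance_at_mean) {
  if (length(deviance_draws) < 100) {
    warn("Fewer than 100 posterior draws; pD and DIC may be unstable.")
  }
  D_bar <- mean(deviance_draws)
  p_D <- D_bar - deviance_at_mean
  tibble::tibble(D_bar = D_bar, D_at_mean = deviance_at_mean,
                 p_D = p_D, DIC = D_bar + p_D)
}
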