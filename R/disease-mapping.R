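#' Specify a disease-mapping model
#'
#' Structure of the Bayesian Poisson model for ward-by-cohort counts of high
#' scorers:
#' \deqn{Y_{jt} \sim \mathrm{Poisson}(E_{jt}\,\theta_{jt}), \qquad
#'   \log\theta_{jt} = \beta_0 + (\beta_1 + u_{1j})\,t + u_{0j} +
#'   \textstyle\sum_k \beta_k x_{jkt}}
#' with exchangeable (unstructured) ward intercepts
#' \eqn{u_{0j} \sim N(0, \sigma^2_{u0})}, an optional differential linear
#' trend \eqn{u_{1j} \sim N(0, \sigma^2_{u1})} per ward (independent of, or
#' correlated with, the intercepts), and ward-level covariates. The cohort
#' covariate is coded `t = year - first year`, so \eqn{\exp(\beta_0)} is the
#' first-cohort baseline rate of high scores. Unstructured ward effects are
#' the default; they model spatial heterogeneity without assuming
#' neighbouring wards are similar, appropriate when a Moran screen of
#' residuals shows no spatial correlation.
#'
#' @param include_slopes Include per-ward differential linear trends?
#' @param correlate_slopes Model (intercept, slope) pairs as bivariate
#'   normal? Requires `include_slopes`.
#' @param covariates Ordered subset of `"prop_off_age"`,
#'   `"prop_most_deprived"`, `"prop_boys"`.
#' @param structured Spatially structured ward intercepts (proper CAR with
#'   autocorrelation 0.95 on the queen-contiguity graph) instead of the
#'   exchangeable default. Off by default: use only when a residual Moran
#'   screen shows spatial correlation. Requires passing `W` to [fit_dm()].
#' @param priors A [prior_config()].
#' @return A `dm_spec` list.
#' @export
dm_spec <- function(include_slopes = FALSE, correlate_slopes = FALSE,
                    covariates = character(), structured = FALSE,
                    priors = prior_config()) {
  check_flag(include_slopes, "include_slopes")
  check_flag(correlate_slopes, "correlate_slopes")
  check_flag(structured, "structured")
  if (correlate_slopes && !include_slopes) {
    abort("`correlate_slopes` requires `include_slopes = TRUE`.")
  }
  allowed <- c("prop_off_age", "prop_most_deprived", "prop_boys")
  bad <- setdiff(covariates, allowed)
  if (length(bad)) abort(sprintf("Unknown covariate(s): %s.", paste(bad, collapse = ", ")))
  structure(list(include_slopes = include_slopes,
                 correlate_slopes = correlate_slopes,
                 covariates = covariates, structured = structured,
                 priors = priors),
            class = "dm_spec")
}

dm_model_string <- function(spec, n_cov) {
  pr <- spec$priors
  prec_beta <- 1 / pr$beta_variance
  lp <- "b0 + b1 * t[i] + u0[ward[i]]"
  if (spec$include_slopes) lp <- paste0(lp, " + u1[ward[i]] * t[i]")
  if (n_cov > 0) lp <- paste0(lp, " + inprod(beta[], X[i,])")

  effects <- if (spec$include_slopes && spec$correlate_slopes) {
    # bivariate-normal intercept/slope pairs; Wishart prior on the 2x2 precision
    "
  for (j in 1:J) {
    u[j, 1:2] ~ dmnorm(zero2[], TauU[,])
    u0[j] <- u[j, 1]
    u1[j] <- u[j, 2]
  }
  TauU[1:2, 1:2] ~ dwish(Rw[,], 3)
  SigmaU[1:2, 1:2] <- inverse(TauU[,])
  sigma2_u0 <- SigmaU[1, 1]
  sigma2_u1 <- SigmaU[2, 2]
  cor_u <- SigmaU[1, 2] / sqrt(SigmaU[1, 1] * SigmaU[2, 2])"
  } else if (spec$include_slopes) {
    sprintf("
  for (j in 1:J) {
    u0[j] ~ dnorm(0, tau0)
    u1[j] ~ dnorm(0, tau1)
  }
  tau0 ~ dgamma(%g, %g)
  tau1 ~ dgamma(%g, %g)
  sigma2_u0 <- 1 / tau0
  sigma2_u1 <- 1 / tau1", pr$prec_shape, pr$prec_rate, pr$prec_shape, pr$prec_rate)
  } else if (isTRUE(spec$structured)) {
    # proper CAR: precision tau0 * (D - 0.95 W), supplied as data Pcar
    sprintf("
  u0[1:J] ~ dmnorm(zeroJ[], tau0 * Pcar[,])
  tau0 ~ dgamma(%g, %g)
  sigma2_u0 <- 1 / tau0", pr$prec_shape, pr$prec_rate)
  } else {
    sprintf("
  for (j in 1:J) { u0[j] ~ dnorm(0, tau0) }
  tau0 ~ dgamma(%g, %g)
  sigma2_u0 <- 1 / tau0", pr$prec_shape, pr$prec_rate)
  }

  cov_prior <- if (n_cov > 0) {
    sprintf("\n  for (k in 1:K) { beta[k] ~ dnorm(0, %g) }", prec_beta)
  } else ""

  sprintf("
model {
  for (i in 1:N) {
    Y[i] ~ dpois(mu[i])
    log(mu[i]) <- log(E[i]) + %s
  }%s
  b0 ~ dnorm(0, %g)
  b1 ~ dnorm(0, %g)%s
}", lp, effects, prec_beta, prec_beta, cov_prior)
}

#' Fit the Poisson disease-mapping model
#'
#' MCMC fit (via JAGS) of the model described in [dm_spec()] to ward-by-
#' cohort counts of high scorers, with the count of assessed children as the
#' exposure offset. Posterior draws of the ward effects are recentred to sum
#' to zero within each draw, sweeping the mean into the intercept (and the
#' slope-mean into the overall trend), which identifies \eqn{\beta_0} and
#' \eqn{\beta_1}. Convergence is assessed with the Gelman-Rubin statistic;
#' the fit is flagged unconverged when any parameter's Rhat exceeds
#' `rhat_threshold`.
#'
#' @param counts Ward-year counts from [aggregate_ward_year()], columns
#'   `ward_id`, `cohort`, `Y`, `E` and any requested covariates; every `E`
#'   must be positive.
#' @param spec A [dm_spec()].
#' @param n_iter,n_burnin,n_adapt,n_chains,thin MCMC settings.
#' @param seed Integer seed (chains are seeded deterministically from it).
#' @param rhat_threshold Gelman-Rubin threshold above which the fit is
#'   flagged unconverged.
#' @param quiet Suppress JAGS progress output.
#' @param W Ward adjacency matrix, required only for `structured` specs.
#' @return A `dm_fit` object: recentred posterior draws, log-scale
#'   summaries, Rhat table, deviance/DIC breakdown, and the prepared data.
#' @export
fit_dm <- function(counts, spec = dm_spec(), n_iter = 2000, n_burnin = 1000,
                   n_adapt = 500, n_chains = 4, thin = 1, seed = NULL,
                   rhat_threshold = 1.05, quiet = TRUE, W = NULL) {
  if (any(counts$E <= 0)) abort("Every ward-year must have exposure E > 0.")
  if (any(counts$Y < 0) || any(counts$Y > counts$E)) {
    abort("Counts must satisfy 0 <= Y <= E.")
  }
  ward_levels <- sort(unique(counts$ward_id))
  ward <- match(counts$ward_id, ward_levels)
  t_step <- counts$cohort - min(counts$cohort)
  n_cov <- length(spec$covariates)
  missing_cov <- setdiff(spec$covariates, names(counts))
  if (length(missing_cov)) {
    abort(sprintf("`counts` is missing covariate column(s): %s.",
                  paste(missing_cov, collapse = ", ")))
  }
  data <- list(N = nrow(counts), J = length(ward_levels),
               Y = counts$Y, E = counts$E, t = t_step, ward = ward)
  if (n_cov > 0) {
    data$X <- as.matrix(counts[, spec$covariates, drop = FALSE])
    data$K <- n_cov
  }
  if (spec$include_slopes && spec$correlate_slopes) {
    data$zero2 <- c(0, 0)
    data$Rw <- diag(2) * 0.01
  }
  if (isTRUE(spec$structured)) {
    if (spec$include_slopes) {
      abort("The structured ward prior is not combined with random slopes.")
    }
    if (is.null(W) || !all(dim(W) == length(ward_levels))) {
      abort("A structured fit needs the ward adjacency matrix `W` (one row per ward).")
    }
    data$zeroJ <- rep(0, length(ward_levels))
    data$Pcar <- diag(rowSums(W)) - 0.95 * W
  }
  monitors <- c("b0", "b1", "u0", "sigma2_u0")
  if (spec$include_slopes) monitors <- c(monitors, "u1", "sigma2_u1")
  if (spec$include_slopes && spec$correlate_slopes) monitors <- c(monitors, "cor_u")
  if (n_cov > 0) monitors <- c(monitors, "beta")

  run <- run_jags(dm_model_string(spec, n_cov), data, monitors,
                  n_chains = n_chains, n_adapt = n_adapt,
                  n_burnin = n_burnin, n_iter = n_iter, thin = thin,
                  seed = seed, quiet = quiet)
  rhat <- rhat_table(run$chains)
  draws <- run$draws
  u0_cols <- grep("^u0\\[", colnames(draws), value = TRUE)
  draws <- sweep_to_zero(draws, u0_cols, "b0")
  if (spec$include_slopes) {
    u1_cols <- grep("^u1\\[", colnames(draws), value = TRUE)
    draws <- sweep_to_zero(draws, u1_cols, "b1")
  }

  dev <- dm_deviance(draws, data, spec)
  dic <- compute_dic(dev$draws, dev$at_mean)
  converged <- all(rhat$rhat < rhat_threshold, na.rm = TRUE)

  fit <- structure(list(
    draws = draws, chains = run$chains, spec = spec, data = data,
    counts = counts, ward_levels = ward_levels,
    cohort_origin = min(counts$cohort),
    rhat = rhat, dic = dic, converged = converged,
    n_chains = n_chains, seed = seed
  ), class = "dm_fit")
  if (!converged) {
    warn(sprintf("Disease-mapping fit flagged unconverged (max Rhat %.3f).",
                 max(rhat$rhat, na.rm = TRUE)))
  }
  fit
}

# linear predictor draws (S x N) on the log-rate scale, excluding the offset
dm_eta_draws <- function(draws, data, spec) {
  N <- data$N
  eta <- matrix(draws[, "b0"], nrow(draws), N) +
    outer(draws[, "b1"], data$t)
  u0 <- draws[, sprintf("u0[%d]", data$ward), drop = FALSE]
  eta <- eta + u0
  if (spec$include_slopes) {
    u1 <- draws[, sprintf("u1[%d]", data$ward), drop = FALSE]
    eta <- eta + u1 * matrix(data$t, nrow(draws), N, byrow = TRUE)
  }
  if (!is.null(data$X)) {
    bcols <- node_cols(draws, "beta", data$K)
    eta <- eta + draws[, bcols, drop = FALSE] %*% t(data$X)
  }
  eta
}

dm_deviance <- function(draws, data, spec, max_draws = 1000) {
  idx <- if (nrow(draws) > max_draws) {
    round(seq(1, nrow(draws), length.out = max_draws))
  } else seq_len(nrow(draws))
  eta <- dm_eta_draws(draws[idx, , drop = FALSE], data, spec)
  mu <- exp(sweep(eta, 2, log(data$E), `+`))
  dev_draws <- -2 * vapply(seq_along(idx), function(s) {
    sum(dpois(data$Y, mu[s, ], log = TRUE))
  }, numeric(1))
  eta_mean <- dm_eta_draws(matrix(colMeans(draws), 1,
                                  dimnames = list(NULL, colnames(draws))),
                           data, spec)
  mu_mean <- exp(eta_mean[1, ] + log(data$E))
  list(draws = dev_draws, at_mean = -2 * sum(dpois(data$Y, mu_mean, log = TRUE)))
}

#' @export
print.dm_fit <- function(x, ...) {
  cat(sprintf("<dm_fit> Poisson disease-mapping model: %d ward-years, %d wards\n",
              x$data$N, x$data$J))
  cat(sprintf("  slopes: %s, covariates: %s\n",
              x$spec$include_slopes,
              if (length(x$spec$covariates)) paste(x$spec$covariates, collapse = ", ") else "none"))
  cat(sprintf("  DIC %.1f (pD %.1f), max Rhat %.3f, converged: %s\n",
              x$dic$DIC, x$dic$p_D, max(x$rhat$rhat, na.rm = TRUE), x$converged))
  invisible(x)
}

#' @rdname rr_summaries
#' @export
rr_summaries.dm_fit <- function(fit, force = FALSE, ...) {
  check_converged(fit, force)
  draws <- fit$draws
  fixed_cols <- c("b0", "b1")
  fixed_terms <- c("intercept", "cohort")
  if (length(fit$spec$covariates)) {
    fixed_cols <- c(fixed_cols,
                    node_cols(draws, "beta", length(fit$spec$covariates)))
    fixed_terms <- c(fixed_terms, fit$spec$covariates)
  }
  out <- rr_from_draws(draws, fixed_cols, fixed_terms, "fixed")
  u0_cols <- sprintf("u0[%d]", seq_along(fit$ward_levels))
  out <- dplyr::bind_rows(out, rr_from_draws(
    draws, u0_cols, sprintf("ward_%s", fit$ward_levels), "ward"))
  if (fit$spec$include_slopes) {
    u1_cols <- sprintf("u1[%d]", seq_along(fit$ward_levels))
    out <- dplyr::bind_rows(out, rr_from_draws(
      draws, u1_cols, sprintf("ward_%s", fit$ward_levels), "ward_slope"))
  }
  out
}

#' Forward model building by DIC
#'
#' Starting from the base model (cohort trend plus unstructured ward
#' intercepts), candidate terms are added one at a time in the given order
#' and retained or dropped by the Deviance Information Criterion. A random
#' term (slopes, or the preschool effect in the multilevel build) is retained
#' only when it improves the DIC by more than `dic_tol_random`; a covariate
#' is retained unless dropping it would lower the DIC by more than `dic_tol`
#' (default 1). Covariates whose removal does not improve fit therefore stay
#' in the model, while random terms must earn their place by more than the
#' chance wobble of the DIC estimate.
#'
#' @inheritParams fit_dm
#' @param candidates Terms in build order: any of `"slopes"` plus covariate
#'   names.
#' @param dic_tol Retention tolerance for covariates.
#' @param dic_tol_random Minimum DIC improvement a random term must deliver
#'   to be retained; DIC differences below about 5 are conventionally not
#'   considered meaningful, and the conditional-focus DIC lets spurious
#'   random effects absorb a few points of deviance by chance.
#' @param ... Passed to [fit_dm()] (MCMC settings).
#' @return List with `spec` (final [dm_spec()]), `fit` (final fit) and
#'   `ledger` (tibble: step, term, DIC without/with, retained).
#' @export
forward_build_dm <- function(counts,
                             candidates = c("slopes", "prop_off_age",
                                            "prop_most_deprived", "prop_boys"),
                             dic_tol = 1, dic_tol_random = 5, seed = NULL,
                             ...) {
  current <- dm_spec()
  fit <- fit_dm(counts, current, seed = seed, ...)
  ledger <- tibble::tibble(step = 0L, term = "base",
                           dic_without = NA_real_, dic_with = fit$dic$DIC,
                           retained = TRUE)
  for (s in seq_along(candidates)) {
    term <- candidates[s]
    cand <- if (term == "slopes") {
      dm_spec(include_slopes = TRUE, correlate_slopes = FALSE,
              covariates = current$covariates, priors = current$priors)
    } else {
      dm_spec(include_slopes = current$include_slopes,
              correlate_slopes = current$correlate_slopes,
              covariates = c(current$covariates, term), priors = current$priors)
    }
    cand_fit <- fit_dm(counts, cand, seed = if (is.null(seed)) NULL else seed + s, ...)
    dic_without <- fit$dic$DIC
    dic_with <- cand_fit$dic$DIC
    keep <- if (!cand_fit$converged) {
      FALSE
    } else if (term == "slopes") {
      dic_with < dic_without - dic_tol_random
    } else {
      dic_with < dic_without + dic_tol
    }
    ledger <- dplyr::bind_rows(ledger, tibble::tibble(
      step = s, term = term, dic_without = dic_without, dic_with = dic_with,
      retained = keep && cand_fit$converged
    ))
    if (!cand_fit$converged) {
      ledger$term[nrow(ledger)] <- paste0(term, " (fit invalid)")
    } else if (keep) {
      current <- cand
      fit <- cand_fit
    }
  }
  list(spec = current, fit = fit, ledger = ledger)
}

#' Gaussian disease-mapping variant for ward median scores
#'
#' Sensitivity analysis replacing the high-score count outcome with the
#' median total difficulties score per ward-year:
#' \deqn{m_{jt} \sim N(\beta_0 + (\beta_1 + u_{1j})t + u_{0j},\ \sigma^2_e)}
#' with the same random-effect structure as [fit_dm()]. A ward variance
#' posterior concentrated at zero indicates no heterogeneity in median
#' scores between wards.
#'
#' @inheritParams fit_dm
#' @return A `dm_median_fit` with draws, summaries and the ward-variance
#'   posterior.
#' @export
fit_dm_median <- function(counts, spec = dm_spec(), n_iter = 2000,
                          n_burnin = 1000, n_adapt = 500, n_chains = 4,
                          thin = 1, seed = NULL, rhat_threshold = 1.05,
                          quiet = TRUE) {
  if (!"median_score" %in% names(counts)) {
    abort("`counts` must carry a `median_score` column.")
  }
  if (length(unique(counts$cohort)) < 2) {
    abort(paste("A single cohort cannot identify the linear trend;",
                "the median-outcome variant needs >= 2 cohorts."))
  }
  pr <- spec$priors
  ward_levels <- sort(unique(counts$ward_id))
  if (sd(counts$median_score) < 1e-12) {
    # a constant outcome is degenerate for MCMC (the residual precision is
    # unbounded); the posterior for every variance component collapses at 0
    inform("All ward medians are identical; returning the degenerate fit with zero heterogeneity.")
    return(structure(list(
      draws = NULL, chains = NULL, spec = spec, data = NULL, counts = counts,
      ward_levels = ward_levels, rhat = tibble::tibble(parameter = character(),
                                                       rhat = numeric()),
      ward_variance = tibble::tibble(estimate = 0, conf.low = 0, conf.high = 0),
      converged = TRUE, seed = seed
    ), class = "dm_median_fit"))
  }
  data <- list(N = nrow(counts), J = length(ward_levels),
               m = counts$median_score,
               t = counts$cohort - min(counts$cohort),
               ward = match(counts$ward_id, ward_levels))
  slope_block <- if (spec$include_slopes) {
    sprintf("u1[j] ~ dnorm(0, tau1)\n  }\n  tau1 ~ dgamma(%g, %g)\n  sigma2_u1 <- 1 / tau1",
            pr$prec_shape, pr$prec_rate)
  } else "}"
  lp <- if (spec$include_slopes) "b0 + (b1 + u1[ward[i]]) * t[i] + u0[ward[i]]" else
    "b0 + b1 * t[i] + u0[ward[i]]"
  model <- sprintf("
model {
  for (i in 1:N) {
    m[i] ~ dnorm(%s, tau_e)
  }
  for (j in 1:J) {
    u0[j] ~ dnorm(0, tau0)
  %s
  tau0 ~ dgamma(%g, %g)
  tau_e ~ dgamma(%g, %g)
  sigma2_u0 <- 1 / tau0
  sigma2_e <- 1 / tau_e
  b0 ~ dnorm(0, %g)
  b1 ~ dnorm(0, %g)
}", lp, slope_block, pr$prec_shape, pr$prec_rate, pr$prec_shape, pr$prec_rate,
    1 / pr$beta_variance, 1 / pr$beta_variance)
  monitors <- c("b0", "b1", "u0", "sigma2_u0", "sigma2_e")
  if (spec$include_slopes) monitors <- c(monitors, "u1", "sigma2_u1")
  run <- run_jags(model, data, monitors, n_chains = n_chains,
                  n_adapt = n_adapt, n_burnin = n_burnin, n_iter = n_iter,
                  thin = thin, seed = seed, quiet = quiet)
  rhat <- rhat_table(run$chains)
  draws <- sweep_to_zero(run$draws,
                         grep("^u0\\[", colnames(run$draws), value = TRUE), "b0")
  s2 <- draws[, "sigma2_u0"]
  structure(list(
    draws = draws, chains = run$chains, spec = spec, data = data,
    counts = counts, ward_levels = ward_levels, rhat = rhat,
    ward_variance = tibble::tibble(
      estimate = mean(s2),
      conf.low = quantile(s2, 0.025), conf.high = quantile(s2, 0.975)),
    converged = all(rhat$rhat < rhat_threshold, na.rm = TRUE),
    seed = seed
  ), class = "dm_median_fit")
}

#' @export
print.dm_median_fit <- function(x, ...) {
  cat(sprintf("<dm_median_fit> Gaussian ward-median model: %d ward-years\n", x$data$N))
  cat(sprintf("  ward variance %.4f (%.4f-%.4f)\n",
              x$ward_variance$estimate, x$ward_variance$conf.low,
              x$ward_variance$conf.high))
  invisible(x)
}

#' Conjugate single-rate Poisson fit (MCMC machinery check)
#'
#' Intercept-only Poisson rate model with a conjugate Gamma(a, b) prior on
#' the common rate \eqn{\theta}: \eqn{Y_i \sim \mathrm{Poisson}(E_i\theta)}.
#' The posterior is available in closed form,
#' \eqn{\theta \mid Y \sim \mathrm{Gamma}(a + \sum Y_i,\ b + \sum E_i)},
#' so the MCMC draws can be validated against an exact reference.
#'
#' @param Y,E Count and exposure vectors.
#' @param a,b Gamma prior shape and rate.
#' @inheritParams fit_dm
#' @return List with `draws` (vector of theta draws) and `closed_form`
#'   (shape/rate of the exact posterior).
#' @export
fit_rate_conjugate <- function(Y, E, a = 1, b = 1, n_iter = 4000,
                               n_burnin = 500, n_chains = 2, seed = NULL) {
  model <- sprintf("
model {
  for (i in 1:N) { Y[i] ~ dpois(E[i] * theta) }
  theta ~ dgamma(%g, %g)
}", a, b)
  run <- run_jags(model, list(N = length(Y), Y = Y, E = E), "theta",
                  n_chains = n_chains, n_adapt = 300, n_burnin = n_burnin,
                  n_iter = n_iter, seed = seed)
  list(draws = as.numeric(run$draws[, "theta"]),
       closed_form = c(shape = a + sum(Y), rate = b + sum(E)))
}
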