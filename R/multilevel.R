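#' Specify the multilevel model for individual scores
#'
#' Structure of the Bayesian zero-inflated negative binomial model for a
#' child's total difficulties score:
#' \deqn{Y_{ijk} \sim \mathrm{ZINB}(\lambda_{ijk},\ p,\ r), \qquad
#'   \log\lambda_{ijk} = \beta_0 + (\beta_1 + v_{1j})t + \alpha_k + v_{0j}
#'     + \beta_\phi x_i}
#' for child i in ward j and preschool k. Preschool effects
#' \eqn{\alpha_k \sim N(0, \sigma^2_\alpha)} and ward intercepts
#' \eqn{v_{0j} \sim N(0, \sigma^2_{v0})} are cross-classified (a preschool
#' draws children from more than one ward, so neither factor nests the
#' other). Individual covariates are sex, age centred on 59 months and
#' squared (a single quadratic term: difficulties are higher at both ends of
#' the school-start age range), and deprivation quintile entered as four
#' dummies against the least-deprived reference. Zero inflation is a
#' structural-zero mixture with global mixing weight `p`; `p` and the
#' overdispersion `r` are global scalars.
#'
#' @param include_preschool Include the preschool random effect?
#' @param include_slopes Include per-ward differential linear trends?
#' @param covariates Ordered subset of `"sex"`, `"age_centred_squared"`,
#'   `"deprivation"`.
#' @param zero_inflation Use the ZINB likelihood (`TRUE`, default) or plain
#'   negative binomial.
#' @param priors A [prior_config()].
#' @return An `ml_spec` list.
#' @export
ml_spec <- function(include_preschool = TRUE, include_slopes = FALSE,
                    covariates = c("sex", "age_centred_squared", "deprivation"),
                    zero_inflation = TRUE,
                    priors = prior_config()) {
  check_flag(include_preschool, "include_preschool")
  check_flag(include_slopes, "include_slopes")
  check_flag(zero_inflation, "zero_inflation")
  allowed <- c("sex", "age_centred_squared", "deprivation")
  bad <- setdiff(covariates, allowed)
  if (length(bad)) abort(sprintf("Unknown covariate(s): %s.", paste(bad, collapse = ", ")))
  structure(list(include_preschool = include_preschool,
                 include_slopes = include_slopes,
                 covariates = covariates, zero_inflation = zero_inflation,
                 priors = priors),
            class = "ml_spec")
}

ml_model_string <- function(spec, n_cov, include_ward) {
  pr <- spec$priors
  prec_beta <- 1 / pr$beta_variance
  lp <- "b0 + b1 * t[i]"
  if (include_ward) lp <- paste0(lp, " + v0[ward[i]]")
  if (spec$include_slopes) lp <- paste0(lp, " + v1[ward[i]] * t[i]")
  if (spec$include_preschool) lp <- paste0(lp, " + a[pre[i]]")
  if (n_cov > 0) lp <- paste0(lp, " + inprod(beta[], X[i,])")

  lik <- if (spec$zero_inflation) {
    # structural-zero mixture: zero[i] = 1 forces the NB success probability
    # to 1, a point mass at zero
    "
    zero[i] ~ dbern(p)
    pnb[i] <- r / (r + (1 - zero[i]) * lambda[i])
    y[i] ~ dnegbin(pnb[i], r)"
  } else {
    "
    pnb[i] <- r / (r + lambda[i])
    y[i] ~ dnegbin(pnb[i], r)"
  }

  blocks <- character()
  if (include_ward) {
    blocks <- c(blocks, sprintf(
      "  for (j in 1:J) { v0[j] ~ dnorm(0, tauv) }\n  tauv ~ dgamma(%g, %g)\n  sigma2_v0 <- 1 / tauv",
      pr$prec_shape, pr$prec_rate))
  }
  if (spec$include_slopes) {
    blocks <- c(blocks, sprintf(
      "  for (j in 1:J) { v1[j] ~ dnorm(0, tau1) }\n  tau1 ~ dgamma(%g, %g)\n  sigma2_v1 <- 1 / tau1",
      pr$prec_shape, pr$prec_rate))
  }
  if (spec$include_preschool) {
    blocks <- c(blocks, sprintf(
      "  for (k in 1:K) { a[k] ~ dnorm(0, taua) }\n  taua ~ dgamma(%g, %g)\n  sigma2_a <- 1 / taua",
      pr$prec_shape, pr$prec_rate))
  }
  if (n_cov > 0) {
    blocks <- c(blocks, sprintf(
      "  for (c in 1:C) { beta[c] ~ dnorm(0, %g) }", prec_beta))
  }
  if (spec$zero_inflation) {
    blocks <- c(blocks, "  p ~ dunif(0, 1)")
  }
  blocks <- c(blocks, "  r ~ dunif(0.01, 50)")

  sprintf("
model {
  for (i in 1:N) {%s
    log(lambda[i]) <- %s
  }
%s
  b0 ~ dnorm(0, %g)
  b1 ~ dnorm(0, %g)
}", lik, lp, paste(blocks, collapse = "\n"), prec_beta, prec_beta)
}

# design matrix for the individual covariates; deprivation enters as four
# dummies against the least-deprived quintile 5
ml_design <- function(records, covariates) {
  X <- NULL
  terms <- character()
  if ("sex" %in% covariates) {
    X <- cbind(X, male = as.numeric(records$sex == "male"))
    terms <- c(terms, "male")
  }
  if ("age_centred_squared" %in% covariates) {
    X <- cbind(X, age_c_sq = (records$age_months - 59)^2)
    terms <- c(terms, "age_centred_squared")
  }
  if ("deprivation" %in% covariates) {
    for (q in 4:1) {
      X <- cbind(X, as.numeric(records$deprivation_quintile == q))
      terms <- c(terms, sprintf("deprivation_q%d", q))
    }
  }
  list(X = X, terms = terms)
}

#' Fit the zero-inflated negative binomial multilevel model
#'
#' MCMC fit (via JAGS) of the model described in [ml_spec()] to individual
#' child records. Preschool and ward effects are estimated as crossed (not
#' nested) random effects; their posterior draws are recentred to sum to
#' zero within each draw, with the means swept into the intercept so
#' \eqn{\beta_0} is identifiable.
#'
#' Degenerate designs are handled explicitly: an all-zero outcome leaves the
#' zero-inflation weight unidentifiable and the fit aborts; a single ward
#' (or single preschool) cannot support the corresponding variance component,
#' which is dropped with a warning.
#'
#' @param records Child records with `ward_id`, `preschool_id`, `cohort`,
#'   `total_score`, `sex`, `age_months`, `deprivation_quintile`.
#' @param spec An [ml_spec()].
#' @inheritParams fit_dm
#' @return An `ml_fit` object: recentred posterior draws, Rhat table,
#'   deviance/DIC breakdown, and index maps for wards and preschools.
#' @export
fit_ml <- function(records, spec = ml_spec(), n_iter = 1000, n_burnin = 500,
                   n_adapt = 300, n_chains = 2, thin = 1, seed = NULL,
                   rhat_threshold = 1.05, quiet = TRUE) {
  y <- records$total_score
  if (anyNA(y)) abort("`total_score` must be complete; filter exclusions first.")
  if (all(y == 0)) {
    abort(paste("All outcomes are zero: the zero-inflation weight is not",
                "identifiable and no fit is attempted."))
  }
  ward_levels <- sort(unique(records$ward_id))
  pre_levels <- sort(unique(records$preschool_id))
  include_ward <- length(ward_levels) >= 2
  if (!include_ward) {
    warn("Only one ward present; the ward variance component is excluded.")
  }
  spec_used <- spec
  if (spec$include_preschool && length(pre_levels) < 2) {
    warn("Only one preschool present; the preschool variance component is excluded.")
    spec_used$include_preschool <- FALSE
  }
  if (spec$include_slopes && !include_ward) spec_used$include_slopes <- FALSE

  des <- ml_design(records, spec_used$covariates)
  n_cov <- length(des$terms)
  data <- list(N = nrow(records), y = y,
               t = records$cohort - min(records$cohort))
  if (include_ward) {
    data$J <- length(ward_levels)
    data$ward <- match(records$ward_id, ward_levels)
  }
  if (spec_used$include_preschool) {
    data$K <- length(pre_levels)
    data$pre <- match(records$preschool_id, pre_levels)
  }
  if (n_cov > 0) {
    data$X <- des$X
    data$C <- n_cov
  }
  monitors <- c("b0", "b1", "r")
  if (spec_used$zero_inflation) monitors <- c(monitors, "p")
  if (include_ward) monitors <- c(monitors, "v0", "sigma2_v0")
  if (spec_used$include_slopes) monitors <- c(monitors, "v1", "sigma2_v1")
  if (spec_used$include_preschool) monitors <- c(monitors, "a", "sigma2_a")
  if (n_cov > 0) monitors <- c(monitors, "beta")

  # moment-based starting values put the chains near the data scale, cutting
  # the burn-in needed for the intercept and mixture weight
  p0 <- min(0.5, max(0.02, mean(y == 0) / 2))
  inits_base <- list(b0 = log(mean(y) / (1 - p0) + 0.1), b1 = 0, r = 2)
  if (spec_used$zero_inflation) inits_base$p <- p0
  if (n_cov > 0) inits_base$beta <- rep(0, n_cov)
  run <- run_jags(ml_model_string(spec_used, n_cov, include_ward), data,
                  monitors, n_chains = n_chains, n_adapt = n_adapt,
                  n_burnin = n_burnin, n_iter = n_iter, thin = thin,
                  seed = seed, quiet = quiet, inits_base = inits_base)
  rhat <- rhat_table(run$chains)
  draws <- run$draws
  if (include_ward) {
    draws <- sweep_to_zero(draws, grep("^v0\\[", colnames(draws), value = TRUE), "b0")
  }
  if (spec_used$include_preschool) {
    draws <- sweep_to_zero(draws, grep("^a\\[", colnames(draws), value = TRUE), "b0")
  }
  if (spec_used$include_slopes) {
    draws <- sweep_to_zero(draws, grep("^v1\\[", colnames(draws), value = TRUE), "b1")
  }

  dev <- ml_deviance(draws, data, spec_used, include_ward)
  dic <- compute_dic(dev$draws, dev$at_mean)
  converged <- all(rhat$rhat < rhat_threshold, na.rm = TRUE)
  fit <- structure(list(
    draws = draws, chains = run$chains, spec = spec_used, data = data,
    records = records, ward_levels = ward_levels, pre_levels = pre_levels,
    include_ward = include_ward, terms = des$terms,
    cohort_origin = min(records$cohort),
    rhat = rhat, dic = dic, converged = converged,
    n_chains = n_chains, seed = seed
  ), class = "ml_fit")
  if (!converged) {
    warn(sprintf("Multilevel fit flagged unconverged (max Rhat %.3f).",
                 max(rhat$rhat, na.rm = TRUE)))
  }
  fit
}

# linear predictor draws (S x N) on the log-mean scale
ml_eta_draws <- function(draws, data, spec, include_ward) {
  N <- data$N
  eta <- matrix(draws[, "b0"], nrow(draws), N) + outer(draws[, "b1"], data$t)
  if (include_ward) {
    eta <- eta + draws[, sprintf("v0[%d]", data$ward), drop = FALSE]
  }
  if (spec$include_slopes) {
    eta <- eta + draws[, sprintf("v1[%d]", data$ward), drop = FALSE] *
      matrix(data$t, nrow(draws), N, byrow = TRUE)
  }
  if (spec$include_preschool) {
    eta <- eta + draws[, sprintf("a[%d]", data$pre), drop = FALSE]
  }
  if (!is.null(data$X)) {
    bcols <- node_cols(draws, "beta", data$C)
    eta <- eta + draws[, bcols, drop = FALSE] %*% t(data$X)
  }
  eta
}

# conditional deviance: -2 log ZINB likelihood at each draw's (beta, effects,
# p, r); the DIC plug-in uses posterior means of the same quantities
ml_deviance <- function(draws, data, spec, include_ward, max_draws = 400) {
  idx <- if (nrow(draws) > max_draws) {
    round(seq(1, nrow(draws), length.out = max_draws))
  } else seq_len(nrow(draws))
  sub <- draws[idx, , drop = FALSE]
  eta <- ml_eta_draws(sub, data, spec, include_ward)
  p <- if (spec$zero_inflation) sub[, "p"] else rep(0, length(idx))
  r <- sub[, "r"]
  dev_draws <- -2 * vapply(seq_along(idx), function(s) {
    zinb_loglik(data$y, exp(eta[s, ]), p[s], r[s])
  }, numeric(1))
  mean_row <- matrix(colMeans(draws), 1, dimnames = list(NULL, colnames(draws)))
  eta_m <- ml_eta_draws(mean_row, data, spec, include_ward)[1, ]
  p_m <- if (spec$zero_inflation) mean(draws[, "p"]) else 0
  at_mean <- -2 * zinb_loglik(data$y, exp(eta_m), p_m, mean(draws[, "r"]))
  list(draws = dev_draws, at_mean = at_mean)
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("<ml_fit> ZINB multilevel model: %d children, %d wards, %d preschools\n",
              x$data$N, length(x$ward_levels), length(x$pre_levels)))
  cat(sprintf("  covariates: %s\n",
              if (length(x$terms)) paste(x$terms, collapse = ", ") else "none"))
  cat(sprintf("  DIC %.1f (pD %.1f), max Rhat %.3f, converged: %s\n",
              x$dic$DIC, x$dic$p_D, max(x$rhat$rhat, na.rm = TRUE), x$converged))
  invisible(x)
}

#' @rdname rr_summaries
#' @export
rr_summaries.ml_fit <- function(fit, force = FALSE, ...) {
  check_converged(fit, force)
  draws <- fit$draws
  fixed_cols <- c("b0", "b1")
  fixed_terms <- c("intercept", "cohort")
  if (length(fit$terms)) {
    fixed_cols <- c(fixed_cols, node_cols(draws, "beta", length(fit$terms)))
    fixed_terms <- c(fixed_terms, fit$terms)
  }
  out <- rr_from_draws(draws, fixed_cols, fixed_terms, "fixed")
  if (fit$include_ward) {
    cols <- sprintf("v0[%d]", seq_along(fit$ward_levels))
    out <- dplyr::bind_rows(out, rr_from_draws(
      draws, cols, sprintf("ward_%s", fit$ward_levels), "ward"))
  }
  if (fit$spec$include_preschool) {
    cols <- sprintf("a[%d]", seq_along(fit$pre_levels))
    out <- dplyr::bind_rows(out, rr_from_draws(
      draws, cols, sprintf("preschool_%s", fit$pre_levels), "preschool"))
  }
  if (fit$spec$include_slopes) {
    cols <- sprintf("v1[%d]", seq_along(fit$ward_levels))
    out <- dplyr::bind_rows(out, rr_from_draws(
      draws, cols, sprintf("ward_%s", fit$ward_levels), "ward_slope"))
  }
  out
}

#' Variance-component summaries of a multilevel fit
#'
#' @param fit An `ml_fit`.
#' @return Tibble with posterior mean and 95% credible interval of each
#'   variance component (and `p`, `r`).
#' @export
ml_variances <- function(fit) {
  cols <- intersect(c("sigma2_a", "sigma2_v0", "sigma2_v1", "p", "r"),
                    colnames(fit$draws))
  posterior_summary(fit$draws, cols)
}

#' @rdname forward_build_dm
#' @param records Child records (multilevel build).
#' @export
forward_build_ml <- function(records,
                             candidates = c("preschool", "slopes", "age",
                                            "sex", "deprivation"),
                             dic_tol = 1, dic_tol_random = 5, seed = NULL,
                             ...) {
  base <- ml_spec(include_preschool = FALSE, include_slopes = FALSE,
                  covariates = character())
  fit <- fit_ml(records, base, seed = seed, ...)
  current <- base
  ledger <- tibble::tibble(step = 0L, term = "base",
                           dic_without = NA_real_, dic_with = fit$dic$DIC,
                           retained = TRUE)
  cov_name <- c(age = "age_centred_squared", sex = "sex",
                deprivation = "deprivation")
  for (s in seq_along(candidates)) {
    term <- candidates[s]
    cand <- current
    if (term == "preschool") {
      cand$include_preschool <- TRUE
    } else if (term == "slopes") {
      cand$include_slopes <- TRUE
    } else {
      cand$covariates <- c(cand$covariates, cov_name[[term]])
    }
    cand_fit <- fit_ml(records, cand, seed = if (is.null(seed)) NULL else seed + s, ...)
    dic_without <- fit$dic$DIC
    dic_with <- cand_fit$dic$DIC
    random_term <- term %in% c("preschool", "slopes")
    keep <- if (!cand_fit$converged) {
      FALSE
    } else if (random_term) {
      dic_with < dic_without - dic_tol_random
    } else {
      dic_with < dic_without + dic_tol
    }
    ledger <- dplyr::bind_rows(ledger, tibble::tibble(
      step = s, term = if (cand_fit$converged) term else paste0(term, " (fit invalid)"),
      dic_without = dic_without, dic_with = dic_with, retained = keep
    ))
    if (keep) {
      current <- cand
      fit <- cand_fit
    }
  }
  list(spec = current, fit = fit, ledger = ledger)
}
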