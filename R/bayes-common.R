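#' Prior configuration shared by both models
#'
#' Weakly informative defaults: fixed effects get zero-mean Gaussian priors
#' with variance 1000 (precision 0.001); each random-effect precision
#' \eqn{1/\sigma^2} gets a Gamma(1, 0.0005) prior, the classic vague choice
#' for variance components in hierarchical disease-mapping models.
#'
#' @param beta_variance Prior variance of fixed effects.
#' @param prec_shape,prec_rate Gamma shape and rate for random-effect
#'   precisions.
#' @return A `prior_config` list.
#' @export
prior_config <- function(beta_variance = 1000, prec_shape = 1,
                         prec_rate = 0.0005) {
  if (beta_variance <= 0 || prec_shape <= 0 || prec_rate <= 0) {
    abort("Prior hyperparameters must be positive.")
  }
  structure(list(beta_variance = beta_variance, prec_shape = prec_shape,
                 prec_rate = prec_rate), class = "prior_config")
}

# Run a JAGS model and return combined draws plus per-chain chains for
# convergence diagnostics. Chain RNGs are seeded deterministically from
# `seed` so a fit is exactly reproducible.
run_jags <- function(model_string, data, monitors, n_chains = 4,
                     n_adapt = 500, n_burnin = 1000, n_iter = 2000,
                     thin = 1, seed = NULL, quiet = TRUE, inits_base = NULL) {
  inits <- NULL
  if (!is.null(seed) || !is.null(inits_base)) {
    inits <- lapply(seq_len(n_chains), function(ch) {
      ini <- inits_base %||% list()
      if (!is.null(seed)) {
        ini$.RNG.name <- "base::Mersenne-Twister"
        ini$.RNG.seed <- (as.double(seed) + 104729 * ch) %% 2147483647
      }
      ini
    })
  }
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_adapt, quiet = quiet)
  if (n_burnin > 0) update(jm, n_burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitors, n.iter = n_iter,
                              thin = thin, progress.bar = "none")
  list(chains = samp, draws = as.matrix(samp))
}

# split-free Gelman-Rubin Rhat per parameter across chains (NA for a single
# chain or a degenerate parameter)
rhat_table <- function(chains) {
  params <- colnames(chains[[1]])
  if (length(chains) < 2) {
    return(tibble::tibble(parameter = params, rhat = NA_real_))
  }
  rhat <- vapply(params, function(p) {
    draws <- sapply(chains, function(ch) as.numeric(ch[, p]))
    if (sd(draws) < 1e-12) return(NA_real_)
    m <- ncol(draws); n <- nrow(draws)
    means <- colMeans(draws)
    B <- n * var(means)
    Wv <- mean(apply(draws, 2, var))
    if (Wv < 1e-300) return(NA_real_)
    sqrt(((n - 1) / n * Wv + B / n) / Wv)
  }, numeric(1))
  tibble::tibble(parameter = params, rhat = unname(rhat))
}

# per-draw recentring that imposes the sum-to-zero constraint on a random
# effect block, sweeping its mean into the given fixed effect
sweep_to_zero <- function(draws, effect_cols, into_col) {
  if (length(effect_cols) == 0) return(draws)
  m <- rowMeans(draws[, effect_cols, drop = FALSE])
  draws[, effect_cols] <- draws[, effect_cols, drop = FALSE] - m
  draws[, into_col] <- draws[, into_col] + m
  draws
}

# column names of a monitored vector node; JAGS drops the index for
# length-one vectors
node_cols <- function(draws, name, K) {
  cols <- grep(sprintf("^%s\\[", name), colnames(draws), value = TRUE)
  if (length(cols) == 0 && K >= 1 && name %in% colnames(draws)) cols <- name
  if (length(cols) != K) {
    abort(sprintf("Expected %d columns for node `%s`, found %d.", K, name,
                  length(cols)))
  }
  cols
}

# posterior summary tibble (log scale) for selected columns
posterior_summary <- function(draws, cols, terms = cols) {
  sub <- draws[, cols, drop = FALSE]
  tibble::tibble(
    term = terms,
    estimate = unname(colMeans(sub)),
    std.error = unname(apply(sub, 2, sd)),
    conf.low = unname(apply(sub, 2, quantile, 0.025)),
    conf.high = unname(apply(sub, 2, quantile, 0.975))
  )
}

# RR-scale summary with exceedance probabilities Pr(RR > 1)
rr_from_draws <- function(draws, cols, terms, type) {
  ed <- exp(draws[, cols, drop = FALSE])
  exc <- unname(colMeans(ed > 1))
  tibble::tibble(
    term = terms,
    type = type,
    rr = unname(colMeans(ed)),
    rr_lo = unname(apply(ed, 2, quantile, 0.025)),
    rr_hi = unname(apply(ed, 2, quantile, 0.975)),
    exceedance = exc,
    flagged = exc >= 0.8
  )
}

#' Relative-rate and exceedance summaries of a fitted model
#'
#' Exponentiates posterior draws into relative rates (RR): for fixed effects
#' the RR per unit covariate change, for ward/preschool random intercepts the
#' RR of that area or institution relative to the average, and for
#' differential slopes the extra trend multiplier. Reports the posterior
#' mean, the central 95% credible interval, and the exceedance probability
#' Pr(RR > 1); areas with exceedance at or above 0.8 are flagged as
#' high-certainty elevations.
#'
#' @param fit A fitted `dm_fit` or `ml_fit`.
#' @param force Summarise even when convergence diagnostics failed?
#' @param ... Unused.
#' @return Tibble with `term`, `type`, `rr`, `rr_lo`, `rr_hi`, `exceedance`,
#'   `flagged`.
#' @export
rr_summaries <- function(fit, force = FALSE, ...) {
  UseMethod("rr_summaries")
}

check_converged <- function(fit, force) {
  if (!isTRUE(fit$converged) && !force) {
    abort(paste("Fit did not pass convergence diagnostics (max Rhat",
                sprintf("%.3f); rerun with longer chains or use `force = TRUE`.",
                        max(fit$rhat$rhat, na.rm = TRUE))))
  }
}
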