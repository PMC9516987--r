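#' Posterior-predictive simulations from a fitted model
#'
#' Draws `n_sim` replicate outcome vectors from the fitted likelihood, each
#' replicate conditioning on one randomly chosen posterior draw of all
#' parameters (fixed effects, random effects, and for the multilevel model
#' the zero-inflation and overdispersion parameters).
#'
#' @param fit A `dm_fit` or `ml_fit`.
#' @param n_sim Number of replicate data sets.
#' @param seed Integer seed.
#' @return n_obs x n_sim matrix of simulated outcomes.
#' @export
simulate_outcomes <- function(fit, n_sim = 250, seed = NULL) {
  UseMethod("simulate_outcomes")
}

#' @export
simulate_outcomes.dm_fit <- function(fit, n_sim = 250, seed = NULL) {
  with_seed(seed, {
    pick <- sample.int(nrow(fit$draws), n_sim, replace = TRUE)
    eta <- dm_eta_draws(fit$draws[pick, , drop = FALSE], fit$data, fit$spec)
    mu <- exp(sweep(eta, 2, log(fit$data$E), `+`))
    sapply(seq_len(n_sim), function(s) rpois(fit$data$N, mu[s, ]))
  })
}

#' @export
simulate_outcomes.ml_fit <- function(fit, n_sim = 250, seed = NULL) {
  with_seed(seed, {
    pick <- sample.int(nrow(fit$draws), n_sim, replace = TRUE)
    sub <- fit$draws[pick, , drop = FALSE]
    eta <- ml_eta_draws(sub, fit$data, fit$spec, fit$include_ward)
    p <- if (fit$spec$zero_inflation) sub[, "p"] else rep(0, n_sim)
    r <- sub[, "r"]
    sapply(seq_len(n_sim), function(s) {
      rzinb(fit$data$N, lambda = exp(eta[s, ]), p = p[s], r = r[s])
    })
  })
}

#' Scaled (randomized PIT) residuals of a fitted model
#'
#' Simulates posterior-predictive replicates with [simulate_outcomes()] and
#' ranks each observation among its replicates with uniform tie-breaking
#' (see [pit_residuals()]). Under a correctly specified model the residuals
#' are marginally Uniform(0, 1).
#'
#' @inheritParams simulate_outcomes
#' @param force Compute even for a fit flagged unconverged?
#' @return Tibble with `observation`, `ward_id`, `residual`; the number of
#'   simulations and seed are carried as attributes.
#' @export
scaled_residuals <- function(fit, n_sim = 250, seed = NULL, force = FALSE) {
  check_converged(fit, force)
  observed <- if (inherits(fit, "dm_fit")) fit$data$Y else fit$data$y
  sims <- simulate_outcomes(fit, n_sim = n_sim,
                            seed = if (is.null(seed)) NULL else seed + 1L)
  res <- pit_residuals(observed, sims, seed = seed)
  ward_id <- if (inherits(fit, "dm_fit")) {
    fit$counts$ward_id
  } else {
    fit$records$ward_id
  }
  out <- tibble::tibble(observation = seq_along(res), ward_id = ward_id,
                        residual = res)
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  out
}
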