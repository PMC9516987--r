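#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy posterior summaries of a disease-mapping fit
#'
#' @param x A `dm_fit`.
#' @param exponentiate Report relative rates instead of log-scale
#'   coefficients?
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high` for the fixed effects and variance components.
#' @export
tidy.dm_fit <- function(x, exponentiate = FALSE, ...) {
  cols <- c("b0", "b1")
  terms <- c("intercept", "cohort")
  if (length(x$spec$covariates)) {
    cols <- c(cols, node_cols(x$draws, "beta", length(x$spec$covariates)))
    terms <- c(terms, x$spec$covariates)
  }
  out <- posterior_summary(x$draws, cols, terms)
  if (exponentiate) {
    rr <- rr_from_draws(x$draws, cols, terms, "fixed")
    out$estimate <- rr$rr
    out$conf.low <- rr$rr_lo
    out$conf.high <- rr$rr_hi
  }
  vc_cols <- intersect(c("sigma2_u0", "sigma2_u1", "cor_u"), colnames(x$draws))
  dplyr::bind_rows(out, posterior_summary(x$draws, vc_cols))
}

#' @rdname tidy.dm_fit
#' @export
glance.dm_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$data$N, n_wards = x$data$J,
    D_bar = x$dic$D_bar, p_D = x$dic$p_D, DIC = x$dic$DIC,
    max_rhat = max(x$rhat$rhat, na.rm = TRUE),
    converged = x$converged, n_draws = nrow(x$draws)
  )
}

#' Tidy posterior summaries of a multilevel fit
#'
#' @param x An `ml_fit`.
#' @inheritParams tidy.dm_fit
#' @return Tibble of fixed effects, variance components, zero-inflation and
#'   overdispersion parameters.
#' @export
tidy.ml_fit <- function(x, exponentiate = FALSE, ...) {
  cols <- c("b0", "b1")
  terms <- c("intercept", "cohort")
  if (length(x$terms)) {
    cols <- c(cols, node_cols(x$draws, "beta", length(x$terms)))
    terms <- c(terms, x$terms)
  }
  out <- posterior_summary(x$draws, cols, terms)
  if (exponentiate) {
    rr <- rr_from_draws(x$draws, cols, terms, "fixed")
    out$estimate <- rr$rr
    out$conf.low <- rr$rr_lo
    out$conf.high <- rr$rr_hi
  }
  extra <- intersect(c("sigma2_a", "sigma2_v0", "sigma2_v1", "p", "r"),
                     colnames(x$draws))
  dplyr::bind_rows(out, posterior_summary(x$draws, extra))
}

#' @rdname tidy.ml_fit
#' @export
glance.ml_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$data$N, n_wards = length(x$ward_levels),
    n_preschools = length(x$pre_levels),
    D_bar = x$dic$D_bar, p_D = x$dic$p_D, DIC = x$dic$DIC,
    max_rhat = max(x$rhat$rhat, na.rm = TRUE),
    converged = x$converged, n_draws = nrow(x$draws)
  )
}
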