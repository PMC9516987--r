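#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats rnorm rbinom rnbinom rpois runif rgamma quantile median
#'   sd var dpois dnorm dnbinom pnorm qgamma qnorm setNames aggregate
#' @importFrom utils head modifyList
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so seeded helpers never perturb a session.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.05 -> 0.1`), the convention used
#' when presenting percentages in descriptive tables. Base R's [round()] uses
#' banker's rounding and would print 12.6499... differently at the boundary.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.05, 0.15, 12.649), 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# integer-rank quartiles: lower nearest-rank 25th/75th percentiles, matching
# integer IQRs conventionally printed for integer-valued scores (type 1)
quartiles_nearest_rank <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(c(q25 = NA_real_, q75 = NA_real_))
  q <- quantile(x, probs = c(0.25, 0.75), type = 1, names = FALSE)
  c(q25 = q[1], q75 = q[2])
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}
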