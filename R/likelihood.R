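#' Gamma log-likelihood in the mean-shape parameterisation
#'
#' Sum over observations of the log density of a Gamma distribution with
#' mean `m_t` and shape `r`, i.e. shape `r` and scale `m_t / r`. This is
#' the observation model for percent-of-peak interest values: real-valued,
#' positive, and overdispersed (it approximates a negative binomial on
#' counts in the large-population limit).
#'
#' @param y observed values (a numeric vector or a `trend_series`). Zeros
#'   make the likelihood degenerate; see [fit_fad()] for the zero-handling
#'   rule applied before fitting.
#' @param mean vector of strictly positive means, recycled against `y`.
#' @param r Gamma shape (> 0).
#' @return The log-likelihood (possibly `-Inf` for invalid inputs).
#' @export
#' @examples
#' gamma_loglik(c(10, 20), mean = c(12, 18), r = 50)
gamma_loglik <- function(y, mean, r) {
  if (is.data.frame(y)) y <- y$value
  if (!is.finite(r) || r <= 0) abort("`r` must be positive")
  if (any(!is.finite(mean)) || any(mean <= 0))
    abort("`mean` must be strictly positive (apply the mean floor first)")
  sum(dgamma(y, shape = r, scale = mean / r, log = TRUE))
}

# Zero weeks make the Gamma density degenerate; Trends rounds small volumes
# to zero. The default treatment is interval censoring: a zero week
# contributes P(Y < limit) with limit half the smallest positive observed
# value (0.5 on the integer 0-100 scale), which a model honestly predicting
# a near-zero mean satisfies with probability ~1. The alternative
# "replace" rule substitutes the limit value itself and scores it with the
# density; it penalises decaying tails heavily and is kept only as an
# option. The chosen limit rides along as the "censor_limit" attribute.
prepare_observations <- function(values, zero_handling = "censor") {
  pos <- values[values > 0]
  if (length(pos) < 2)
    abort("degenerate series: fewer than 2 non-zero points")
  lim <- min(pos) / 2
  if (identical(zero_handling, "censor")) {
    y <- values
    attr(y, "censor_limit") <- if (any(values == 0)) lim else 0
  } else {
    y <- values
    y[y == 0] <- lim
    attr(y, "censor_limit") <- 0
  }
  y
}

replace_zero_values <- function(values) {
  pos <- values[values > 0]
  if (length(pos) < 2)
    abort("degenerate series: fewer than 2 non-zero points")
  values[values == 0] <- min(pos) / 2
  values
}

censor_limit_of <- function(y) attr(y, "censor_limit") %||% 0

# log-likelihood of a prepared series for one parameter set, via the
# compiled solve-and-score path
series_loglik <- function(mechanism, dyn, taus, C, I0, A, delta_t, r, y, config) {
  cpp_series_loglik(mech_code(mechanism), dyn, as.integer(taus), as.integer(C),
                    I0, A, delta_t, r, as.numeric(y), config$dt, config$rtol,
                    config$mean_floor_frac, censor_limit_of(y))
}
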