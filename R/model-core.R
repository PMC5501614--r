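#' Trinomial adoption-threshold probability
#'
#' Probability that a susceptible individual canvassing `C` contacts adopts
#' the behaviour: at least `tau_i` of the canvassed contacts are new
#' participants, or fewer than `tau_i` are new but at least `tau_j` are
#' continuing participants. The pair of counts follows a trinomial
#' distribution with cell probabilities `(i_frac, j_frac, 1 - i_frac -
#' j_frac)`; mass outside the support `k + l <= C` is zero. The adoption
#' rate scale `beta` is applied by the caller.
#'
#' @param i_frac fraction of new participants in the population, in \[0, 1\].
#' @param j_frac fraction of continuing participants, in \[0, 1\];
#'   `i_frac + j_frac` must not exceed 1 (beyond numerical tolerance 1e-9).
#' @param C canvass size.
#' @param tau_i,tau_j integer thresholds in `1..C`.
#' @return Probability in \[0, 1\], vectorised over `i_frac`/`j_frac`.
#' @export
#' @examples
#' multinomial_threshold_prob(0.2, 0.1, C = 3, tau_i = 2, tau_j = 2)
multinomial_threshold_prob <- function(i_frac, j_frac, C, tau_i, tau_j) {
  n <- max(length(i_frac), length(j_frac))
  i_frac <- rep_len(i_frac, n); j_frac <- rep_len(j_frac, n)
  if (any(i_frac < 0) || any(j_frac < 0))
    abort("fractions must be non-negative")
  if (any(i_frac + j_frac > 1 + 1e-9))
    abort("`i_frac + j_frac` must not exceed 1")
  C <- as.integer(C)
  if (tau_i < 1 || tau_i > C || tau_j < 1 || tau_j > C)
    abort("thresholds must lie in 1..C")
  cpp_multi_tail(pmin(i_frac, 1), pmin(j_frac, 1), C, as.integer(tau_i), as.integer(tau_j))
}

#' Binomial quitting-threshold probability
#'
#' Upper tail `P(Y >= tau_r)` for `Y ~ Binomial(C, j_frac)`: the probability
#' that at least `tau_r` of `C` canvassed contacts are continuing
#' participants, which triggers quitting in the complex contagion model.
#'
#' @param j_frac fraction of continuing participants, in \[0, 1\].
#' @param C canvass size.
#' @param tau_r integer threshold in `1..C`.
#' @return Probability in \[0, 1\], vectorised over `j_frac`.
#' @export
binomial_threshold_prob <- function(j_frac, C, tau_r) {
  if (any(j_frac < 0) || any(j_frac > 1 + 1e-9))
    abort("`j_frac` must lie in [0, 1]")
  C <- as.integer(C)
  if (tau_r < 1 || tau_r > C) abort("`tau_r` must lie in 1..C")
  cpp_binom_tail(pmin(j_frac, 1), C, as.integer(tau_r))
}

#' Deterministic right-hand side of a contagion model
#'
#' Time derivatives `(dS/dt, dI/dt, dJ/dt, dR/dt)` of the SIJR system at a
#' given state, for either mechanism. The removed compartment is tracked
#' explicitly (`dR/dt` equals the quit flux) so that the components always
#' sum to zero; there is no return to susceptibility.
#'
#' @param state a [compartment_state()] or numeric vector `(S, I, J, R)`.
#'   Fractions are taken relative to the component sum `N`.
#' @param params a [complex_params()] or [simple_params()] object.
#' @return Named numeric vector of the four derivatives.
#' @export
#' @examples
#' p <- simple_params(beta_i = 1.5, beta_j = 0.5, gamma = 0.4, epsilon = 0.7)
#' contagion_rhs(compartment_state(S = 0.98, I = 0.02), p)
contagion_rhs <- function(state, params) {
  x <- as.numeric(state)
  if (length(x) != 4) abort("`state` must have components (S, I, J, R)")
  N <- sum(x)
  if (N <= 0) abort("population size must be positive")
  frac <- x / N
  d <- cpp_rhs(mech_code(mechanism_of(params)), dyn_vec(params),
               taus_vec(params), C_of(params), frac) * N
  setNames(d, c("dS", "dI", "dJ", "dR"))
}
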