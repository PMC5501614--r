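#' Dynamical parameters of the complex (threshold) contagion mechanism
#'
#' In the complex contagion model each susceptible individual canvasses `C`
#' contacts uniformly at random and adopts the behaviour when at least
#' `tau_i` of them are new participants (compartment I), or fewer than
#' `tau_i` are new but at least `tau_j` are continuing participants
#' (compartment J). Participants quit (J to R) when at least `tau_r` of
#' their canvassed contacts are continuing participants. New participants
#' become continuing participants at constant rate `epsilon`.
#'
#' All rates are per week; the population is rescaled to size 1, so `I0` is
#' the initial participating fraction.
#'
#' @param beta adoption rate scale (per week, non-negative).
#' @param tau_i integer adoption threshold on new participants, in `1..C`.
#' @param tau_j integer adoption threshold on continuing participants.
#' @param tau_r integer quitting threshold on continuing participants.
#' @param epsilon rate of the I to J transition (per week).
#' @param I0 initial participating fraction, in (0, 1).
#' @param C canvass size (number of contacts sampled); fixed at 10 for
#'   fitting because it is not separately identifiable from data.
#' @return An object of class `complex_params`.
#' @export
#' @examples
#' complex_params(beta = 5, tau_i = 2, tau_j = 2, tau_r = 2, epsilon = 0.5, I0 = 0.01)
complex_params <- function(beta, tau_i, tau_j, tau_r, epsilon, I0 = 1e-4, C = 10L) {
  C <- as.integer(C)
  tau_i <- as.integer(tau_i); tau_j <- as.integer(tau_j); tau_r <- as.integer(tau_r)
  if (!is.finite(beta) || beta < 0) abort("`beta` must be a non-negative rate")
  if (!is.finite(epsilon) || epsilon < 0) abort("`epsilon` must be a non-negative rate")
  if (C < 1) abort("`C` must be a positive integer")
  for (tau in c(tau_i, tau_j, tau_r))
    if (tau < 1L || tau > C) abort("thresholds must lie in 1..C")
  if (!is.finite(I0) || I0 <= 0 || I0 >= 1) abort("`I0` must lie strictly between 0 and 1")
  structure(
    list(beta = beta, tau_i = tau_i, tau_j = tau_j, tau_r = tau_r,
         epsilon = epsilon, I0 = I0, C = C),
    class = c("complex_params", "dyn_params"))
}

#' Dynamical parameters of the simple (mass-action) contagion mechanism
#'
#' A straightforward SIR-type modification in which the force of adoption is
#' linear in the participating fractions, `beta_i * I + beta_j * J`, and
#' participants quit at constant per-capita rate `gamma`. As in the complex
#' model, new participants become continuing participants at rate `epsilon`.
#'
#' @param beta_i transmission rate from new participants (per week).
#' @param beta_j transmission rate from continuing participants (per week).
#' @param gamma per-capita quitting rate (per week).
#' @param epsilon rate of the I to J transition (per week).
#' @param I0 initial participating fraction, in (0, 1).
#' @return An object of class `simple_params`.
#' @export
simple_params <- function(beta_i, beta_j, gamma, epsilon, I0 = 1e-4) {
  for (v in c(beta_i, beta_j, gamma, epsilon))
    if (!is.finite(v) || v < 0) abort("all rates must be non-negative and finite")
  if (!is.finite(I0) || I0 <= 0 || I0 >= 1) abort("`I0` must lie strictly between 0 and 1")
  structure(
    list(beta_i = beta_i, beta_j = beta_j, gamma = gamma, epsilon = epsilon, I0 = I0),
    class = c("simple_params", "dyn_params"))
}

#' Observation nuisance parameters
#'
#' The observation model links the solved participating fraction
#' `mu(t) = I(t) + J(t)` to percent-of-peak search interest: the week-`t`
#' observation is Gamma-distributed with mean `A * mu(t + delta_t)` and
#' shape `r` (mean-shape parameterisation).
#'
#' @param A relative amplitude (> 0); a larger `A` corresponds to a smaller
#'   imputed fad compared to the data.
#' @param delta_t additive time shift in weeks; a larger `delta_t` moves the
#'   fad curve left.
#' @param r Gamma shape (> 0); larger means less noise at a given mean.
#' @return An object of class `obs_params`.
#' @export
obs_params <- function(A, delta_t = 0, r = 50) {
  if (!is.finite(A) || A <= 0) abort("`A` must be positive")
  if (!is.finite(r) || r <= 0) abort("`r` must be positive")
  if (!is.finite(delta_t)) abort("`delta_t` must be finite")
  structure(list(A = A, delta_t = delta_t, r = r), class = "obs_params")
}

#' Compartment state of the SIJR system
#'
#' Counts (or fractions) of susceptibles, new participants, continuing
#' participants and removed individuals at an instant. The population size
#' `N` is the component sum.
#'
#' @param S,I,J,R non-negative counts or fractions.
#' @return A named numeric vector of class `compartment_state`.
#' @export
compartment_state <- function(S, I, J = 0, R = 0) {
  x <- c(S = S, I = I, J = J, R = R)
  if (any(!is.finite(x)) || any(x < 0)) abort("compartments must be non-negative")
  structure(x, class = "compartment_state")
}

mechanism_of <- function(params) {
  if (inherits(params, "complex_params")) "complex"
  else if (inherits(params, "simple_params")) "simple"
  else abort("`params` must be a complex_params or simple_params object")
}

# flat vectors consumed by the compiled core
dyn_vec <- function(params) {
  if (inherits(params, "complex_params")) c(params$beta, params$epsilon)
  else c(params$beta_i, params$beta_j, params$gamma, params$epsilon)
}

taus_vec <- function(params) {
  if (inherits(params, "complex_params"))
    c(params$tau_i, params$tau_j, params$tau_r)
  else integer(0)
}

C_of <- function(params) if (inherits(params, "complex_params")) params$C else 0L

#' @export
print.complex_params <- function(x, ...) {
  cat("Complex contagion parameters (C =", x$C, ")\n")
  cat(sprintf("  beta = %.4g, epsilon = %.4g, tau = (%d, %d, %d), I0 = %.3g\n",
              x$beta, x$epsilon, x$tau_i, x$tau_j, x$tau_r, x$I0))
  invisible(x)
}

#' @export
print.simple_params <- function(x, ...) {
  cat("Simple contagion parameters\n")
  cat(sprintf("  beta_i = %.4g, beta_j = %.4g, gamma = %.4g, epsilon = %.4g, I0 = %.3g\n",
              x$beta_i, x$beta_j, x$gamma, x$epsilon, x$I0))
  invisible(x)
}
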