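#' Solve the deterministic contagion model
#'
#' Integrates the SIJR system with the population rescaled to `N = 1`,
#' starting from `S(0) = 1 - I0`, `I(0) = I0`, `J(0) = R(0) = 0`, using an
#' adaptive Dormand-Prince 5(4) method with dense output sampled on a fixed
#' grid.
#'
#' @param params a [complex_params()] or [simple_params()] object; `I0` is
#'   taken from it.
#' @param t_max integration horizon in weeks.
#' @param dt output grid step in weeks (default 0.1).
#' @param rtol solver relative tolerance (default 1e-8).
#' @return A tibble of class `fad_trajectory` with columns `time`, `S`,
#'   `I`, `J`, `R`; the parameters and grid step are carried as attributes.
#' @export
#' @examples
#' p <- simple_params(beta_i = 1.5, beta_j = 0.5, gamma = 0.4, epsilon = 0.7, I0 = 0.01)
#' traj <- solve_trajectory(p, t_max = 30)
#' head(traj)
solve_trajectory <- function(params, t_max, dt = 0.1, rtol = 1e-8) {
  if (!is.finite(t_max) || t_max <= 0) abort("`t_max` must be positive")
  m <- tryCatch(
    cpp_solve(mech_code(mechanism_of(params)), dyn_vec(params), taus_vec(params),
              C_of(params), params$I0, t_max, dt, rtol),
    error = function(e) {
      abort(c("ODE solver failed", "x" = conditionMessage(e),
              "i" = paste("parameters:", paste(
                names(params), signif(unlist(params), 4),
                sep = "=", collapse = ", "))))
    })
  out <- tibble::as_tibble(as.data.frame(m))
  class(out) <- c("fad_trajectory", class(out))
  attr(out, "params") <- params
  attr(out, "dt") <- dt
  attr(out, "rtol") <- rtol
  out
}

traj_params <- function(traj) {
  p <- attr(traj, "params")
  if (is.null(p)) abort("trajectory is missing its `params` attribute")
  p
}

# I + J (clamped at 0) at arbitrary times, linear interpolation on the grid;
# times before 0 read the initial value. Extends the solve if needed.
traj_mu <- function(traj, times) {
  tmax_have <- max(traj$time)
  need <- max(times, 0)
  if (need > tmax_have + 1e-9) {
    traj <- solve_trajectory(traj_params(traj), t_max = need + attr(traj, "dt"),
                             dt = attr(traj, "dt"),
                             rtol = attr(traj, "rtol") %||% 1e-8)
  }
  mu <- pmax(traj$I, 0) + pmax(traj$J, 0)
  xout <- pmin(pmax(times, 0), max(traj$time))
  stats::approx(traj$time, mu, xout = xout)$y
}

#' Observation mean of a solved trajectory
#'
#' The Gamma observation model reads the participating fraction
#' `mu(t) = I(t) + J(t)` at shifted model time `t + delta_t` and scales it
#' by the amplitude `A`: the returned value at requested time `t` is
#' `A * mu(t + delta_t)`. Times before the model origin read the initial
#' state; times beyond the solved horizon trigger an extended solve.
#'
#' @param traj a `fad_trajectory` from [solve_trajectory()].
#' @param obs an [obs_params()] object (the shape `r` is not used here).
#' @param times numeric vector of observation times in weeks.
#' @return Numeric vector of observation means, one per requested time.
#' @export
observation_mean <- function(traj, obs, times) {
  if (!inherits(obs, "obs_params")) abort("`obs` must be an obs_params object")
  obs$A * traj_mu(traj, times + obs$delta_t)
}

#' Observation mean of two superposed sub-populations
#'
#' For bimodal fads the total participating fraction is modelled as the sum
#' over two independently parameterised sub-populations of the same
#' mechanism; for the complex mechanism the thresholds must be shared.
#'
#' @param traj_a,traj_b `fad_trajectory` objects from the same mechanism.
#' @param obs_a,obs_b [obs_params()] for each sub-population.
#' @param times numeric vector of observation times in weeks.
#' @return Numeric vector: the elementwise sum of the two observation means.
#' @export
two_population_mean <- function(traj_a, traj_b, obs_a, obs_b, times) {
  pa <- traj_params(traj_a); pb <- traj_params(traj_b)
  if (mechanism_of(pa) != mechanism_of(pb))
    abort("both trajectories must come from the same contagion mechanism")
  if (inherits(pa, "complex_params")) {
    if (pa$tau_i != pb$tau_i || pa$tau_j != pb$tau_j || pa$tau_r != pb$tau_r)
      abort("complex sub-populations must share the thresholds (tau_i, tau_j, tau_r)")
  }
  observation_mean(traj_a, obs_a, times) + observation_mean(traj_b, obs_b, times)
}

#' Export a trajectory as CSV
#'
#' Writes `time, S, I, J, R, mu` with `mu = I + J`.
#'
#' @param traj a `fad_trajectory`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)[, c("time", "S", "I", "J", "R")]
  df$mu <- pmax(df$I, 0) + pmax(df$J, 0)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
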