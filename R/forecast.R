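#' Transfer forecast from a fitted fad to an emerging one
#'
#' Implements forecasting in the style used for the Icebucket Challenge:
#' the dynamical parameters of a previously fitted fad (the transferred
#' hypothesis) are frozen, the observation nuisances `(A, delta_t, I0, r)`
#' are refit by maximum likelihood on the early weeks of the new fad, and
#' the forecast mean plus central 95% Gamma prediction interval is emitted
#' for each week of the horizon. The interval is plug-in: parameter
#' uncertainty is not propagated. The band's Gamma shape applies a
#' degrees-of-freedom correction `r(T-4)/T` (four nuisance
#' parameters estimated from `T` early observations), the analogue of the
#' `n - p` denominator in variance estimates; the uncorrected maximum
#' likelihood shape is reported alongside.
#'
#' @param source_fit a converged single-population `fad_fit` supplying the
#'   dynamics (`beta` and thresholds, or `beta_i`, `beta_j`, `gamma`, plus
#'   `epsilon`).
#' @param target_early a `trend_series` with the early observations of the
#'   new fad (at least 3 non-zero points).
#' @param horizon number of weeks to forecast (from the target's week 0).
#' @param config a [fit_config()] (controls restarts and the solver).
#' @return A tibble of class `fad_forecast` with columns `week`, `mean`,
#'   `lower95`, `upper95`; the refit nuisance parameters, Gamma shape and
#'   a `converged` flag are carried as attributes.
#' @export
transfer_forecast <- function(source_fit, target_early, horizon,
                              config = fit_config()) {
  if (!inherits(source_fit, "fad_fit")) abort("`source_fit` must be a fad_fit")
  if (!source_fit$converged) abort("`source_fit` did not converge")
  if (source_fit$n_subpops != 1)
    abort("transfer forecasting uses a single-population source fit")
  target_early <- as_trend_series(target_early)
  if (sum(target_early$value > 0) < 3)
    abort("`target_early` needs at least 3 non-zero points")
  y <- prepare_observations(target_early$value, config$zero_handling)
  T_ <- length(y)
  cl <- censor_limit_of(y)
  yv <- as.numeric(y)

  mech <- source_fit$mechanism
  dyn_free <- if (mech == "complex")
    c(source_fit$theta[["beta"]], source_fit$theta[["epsilon"]])
  else
    c(source_fit$theta[["beta_i"]], source_fit$theta[["beta_j"]],
      source_fit$theta[["gamma"]], source_fit$theta[["epsilon"]])
  taus <- if (mech == "complex") source_fit$taus else integer(0)
  C <- if (mech == "complex") source_fit$C else 0L

  # refit (A, delta_t, I0, r) on the early data; x = (logA, logr, d, logI0)
  fn <- function(x) {
    ll <- cpp_series_loglik(mech_code(mech), dyn_free, taus, C, exp(x[4]),
                            exp(x[1]), x[3], exp(x[2]), yv,
                            config$dt, config$rtol, config$mean_floor_frac, cl)
    if (is.finite(ll)) -ll else 1e10
  }

  res <- withr::with_seed(config$seed + 2L, {
    src <- c(log(source_fit$theta[["A"]]), log(source_fit$theta[["r"]]),
             source_fit$theta[["delta_t"]], log(source_fit$theta[["I0"]]))
    n <- config$n_restarts
    ymax <- max(yv)
    # early series: allow shifts placing the peak beyond the observed window
    draws <- cbind(
      runif(n, log(0.5 * ymax), log(100 * ymax)),
      runif(n, log(config$r_range[1]), log(config$r_range[2])),
      runif(n, -2 * T_, 2 * T_),
      log(runif(n, config$I0_range[1], config$I0_range[2])))
    starts <- rbind(src, draws)
    best <- list(value = -Inf)
    for (s in seq_len(nrow(starts))) {
      o <- nm(starts[s, ], fn, config$polish_maxit)
      if (-o$value > best$value) best <- list(value = -o$value, par = o$par)
    }
    if (is.finite(best$value)) {
      o <- polish_hybrid(best$par, fn, config$polish_maxit)
      if (-o$value > best$value) best <- list(value = -o$value, par = o$par)
    }
    best
  })
  converged <- is.finite(res$value) && res$value > -1e9
  if (!converged) warn("nuisance refit failed to converge; forecast uses the best value found")

  A <- exp(res$par[1]); r <- exp(res$par[2])
  d <- res$par[3]; I0 <- exp(res$par[4])

  dyn <- if (mech == "complex")
    complex_params(beta = dyn_free[1], tau_i = taus[1], tau_j = taus[2],
                   tau_r = taus[3], epsilon = dyn_free[2], I0 = I0, C = C)
  else
    simple_params(beta_i = dyn_free[1], beta_j = dyn_free[2],
                  gamma = dyn_free[3], epsilon = dyn_free[4], I0 = I0)

  weeks <- seq(0, horizon - 1)
  t_max <- max(2, horizon + max(d, 0) + 1)
  if (t_max > 1200) abort("forecast horizon is beyond the solver range")
  traj <- solve_trajectory(dyn, t_max = t_max, dt = config$dt, rtol = config$rtol)
  m <- pmax(observation_mean(traj, obs_params(A, d, r), weeks),
            config$mean_floor_frac * A)
  # df-corrected shape for the prediction band (4 nuisances refit on T_ points)
  r_band <- r * max(T_ - 4, 1) / T_
  out <- tibble::tibble(
    week = weeks,
    mean = m,
    lower95 = qgamma(0.025, shape = r_band, scale = m / r_band),
    upper95 = qgamma(0.975, shape = r_band, scale = m / r_band))
  class(out) <- c("fad_forecast", class(out))
  attr(out, "obs") <- obs_params(A, d, r)
  attr(out, "r_band") <- r_band
  attr(out, "dyn") <- dyn
  attr(out, "log_lik") <- res$value
  attr(out, "converged") <- converged
  attr(out, "target_early") <- target_early
  out
}

#' Peak timing and duration of a forecast
#'
#' Reports the argmax week of the forecast mean and the duration of
#' popularity, operationalised as the number of consecutive weeks
#' (containing the peak) with mean at least half the peak value.
#'
#' @param forecast a `fad_forecast` (or any data frame with `week` and
#'   `mean` columns).
#' @return A one-row tibble with `peak_week` and
#'   `duration_above_half_peak`.
#' @export
peak_report <- function(forecast) {
  m <- forecast$mean
  ipk <- which.max(m)
  if (m[ipk] <= 0 || ipk == 1 || ipk == length(m))
    abort("forecast mean has no interior peak (monotone or flat mean)")
  above <- m >= m[ipk] / 2
  lo <- ipk
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- ipk
  while (hi < length(m) && above[hi + 1]) hi <- hi + 1
  tibble::tibble(peak_week = forecast$week[ipk],
                 duration_above_half_peak = hi - lo + 1)
}

#' Export a forecast as CSV
#'
#' @param forecast a `fad_forecast`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_forecast_csv <- function(forecast, path) {
  write.csv(as.data.frame(forecast)[, c("week", "mean", "lower95", "upper95")],
            path, row.names = FALSE)
  invisible(path)
}
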