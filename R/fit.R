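#' Fitting configuration
#'
#' Controls the maximum-likelihood search. The complex mechanism is fitted
#' by an exhaustive outer grid over the integer thresholds
#' `(tau_i, tau_j, tau_r)` with seeded random probe points per grid cell, a
#' derivative-free (Nelder-Mead) refinement of the surviving cells, and a
#' final polish of the best cells; the simple mechanism uses multi-restart
#' Nelder-Mead directly. Continuous positivity constraints are enforced by
#' log-transforming `A`, `r`, `I0` and all rates.
#'
#' @param seed integer seed making the whole fit reproducible.
#' @param n_restarts random restarts for the simple fit, the polish stage
#'   and nuisance refits (default 10).
#' @param coarse_probes seeded probe points evaluated in every threshold
#'   grid cell before refinement (default 6).
#' @param prune_margin grid cells whose best probe trails the incumbent
#'   log-likelihood by more than this are not refined (default 50).
#' @param refine_max cap on the number of refined grid cells (default 14).
#' @param refine_maxit,polish_maxit Nelder-Mead iteration caps for the
#'   refinement and polish stages.
#' @param polish_top number of refined cells carried into the polish stage.
#' @param C canvass size, fixed at 10 for fitting (not identifiable).
#' @param tau_grid integer threshold values searched (default `1:C`).
#' @param tau_sweeps maximum coordinate-descent sweeps over the threshold
#'   grid after polishing (default 4).
#' @param dt observation-grid step for the ODE solve, in weeks.
#' @param rtol ODE solver relative tolerance for reported log-likelihoods.
#' @param search_rtol looser solver tolerance used inside the search stages
#'   (the incumbent is always re-optimised at `rtol` before reporting).
#' @param mean_floor_frac model means are floored at this fraction of the
#'   amplitude so the density stays finite before fad onset.
#' @param grade_boundaries AIC-difference boundaries for positive, strong
#'   and very strong evidence.
#' @param multimodal_prominence,multimodal_trough multimodality detector
#'   settings: minimum secondary-peak height as a fraction of the global
#'   peak, and the trough depth (fraction of the smaller peak) required
#'   between two peaks.
#' @param rate_range log-uniform restart range for all rates (per week).
#' @param I0_range uniform restart range for the initial fraction.
#' @param r_range log-uniform restart range for the Gamma shape.
#' @param A_range_factor restart range for the amplitude, as multiples of
#'   the series maximum.
#' @param zero_handling `"censor"` (default) scores rounded-to-zero weeks
#'   by the Gamma probability of falling below the reporting threshold
#'   (half the smallest positive value); `"replace"` substitutes that
#'   threshold value and scores it with the density.
#' @param allow_short fit series that fail the >15-non-zero-points filter.
#' @param force_two_pop always fit two-sub-population models in
#'   [compare_contagion()], regardless of the multimodality detector.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(seed = 1L,
                       n_restarts = 10L,
                       coarse_probes = 6L,
                       prune_margin = 50,
                       refine_max = 14L,
                       refine_maxit = 250L,
                       polish_top = 3L,
                       polish_maxit = 600L,
                       C = 10L,
                       tau_grid = NULL,
                       tau_sweeps = 4L,
                       dt = 0.1,
                       rtol = 1e-8,
                       search_rtol = 1e-6,
                       mean_floor_frac = 1e-6,
                       grade_boundaries = c(positive = 2, strong = 6, very_strong = 10),
                       multimodal_prominence = 0.2,
                       multimodal_trough = 0.5,
                       rate_range = c(0.05, 20),
                       I0_range = c(1e-6, 1e-2),
                       r_range = c(2, 400),
                       A_range_factor = c(0.5, 100),
                       zero_handling = c("censor", "replace"),
                       allow_short = FALSE,
                       force_two_pop = FALSE) {
  zero_handling <- match.arg(zero_handling)
  structure(list(
    seed = as.integer(seed), n_restarts = as.integer(n_restarts),
    coarse_probes = as.integer(coarse_probes), prune_margin = prune_margin,
    refine_max = as.integer(refine_max), refine_maxit = as.integer(refine_maxit),
    polish_top = as.integer(polish_top), polish_maxit = as.integer(polish_maxit),
    C = as.integer(C), tau_grid = as.integer(tau_grid %||% seq_len(C)),
    tau_sweeps = as.integer(tau_sweeps),
    dt = dt, rtol = rtol, search_rtol = search_rtol,
    mean_floor_frac = mean_floor_frac,
    grade_boundaries = grade_boundaries,
    multimodal_prominence = multimodal_prominence,
    multimodal_trough = multimodal_trough,
    rate_range = rate_range, I0_range = I0_range, r_range = r_range,
    A_range_factor = A_range_factor, zero_handling = zero_handling,
    allow_short = isTRUE(allow_short), force_two_pop = isTRUE(force_two_pop)),
    class = "fit_config")
}

# ---------------------------------------------------------------------------
# parameter transforms: x is the unconstrained optimiser vector
# complex single: (log A, log r, delta_t, log I0, log beta, log epsilon)
# simple single:  (log A, log r, delta_t, log I0, log bi, log bj, log gamma, log eps)
# ---------------------------------------------------------------------------

obj_single <- function(mechanism, taus, y, config, rtol = NULL) {
  mech <- mech_code(mechanism)
  C <- config$C
  dt <- config$dt; floor_frac <- config$mean_floor_frac
  rtol <- rtol %||% config$rtol
  cl <- censor_limit_of(y)
  yv <- as.numeric(y)
  if (mechanism == "complex") {
    function(x) {
      ll <- cpp_series_loglik(mech, exp(x[5:6]), taus, C, exp(x[4]),
                              exp(x[1]), x[3], exp(x[2]), yv, dt, rtol,
                              floor_frac, cl)
      if (is.finite(ll)) -ll else 1e10
    }
  } else {
    function(x) {
      ll <- cpp_series_loglik(mech, exp(x[5:8]), integer(0), 0L, exp(x[4]),
                              exp(x[1]), x[3], exp(x[2]), yv, dt, rtol,
                              floor_frac, cl)
      if (is.finite(ll)) -ll else 1e10
    }
  }
}

# Seeded restart points. Rates and the shape are drawn log-uniformly and I0
# uniformly from the configured ranges; the amplitude and time shift of each
# draw are then moment-matched by solving the drawn dynamics once and
# aligning the model peak with the observed peak. Unaligned random draws
# almost never overlap the data, leaving the likelihood flat.
draw_starts <- function(n, mechanism, taus, y, config) {
  T_ <- length(y)
  ypk <- max(y)
  sm <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  pk_data <- which.max(sm) - 1
  n_rates <- if (mechanism == "complex") 2L else 4L
  mech <- mech_code(mechanism)
  out <- matrix(NA_real_, n, 4 + n_rates)
  for (s in seq_len(n)) {
    rates <- exp(runif(n_rates, log(config$rate_range[1]), log(config$rate_range[2])))
    I0 <- runif(1, config$I0_range[1], config$I0_range[2])
    sol <- tryCatch(
      cpp_solve(mech, rates, taus, config$C, I0, 2 * T_, 1.0, 1e-5),
      error = function(e) NULL)
    if (is.null(sol)) {
      A <- 10 * ypk; d <- 0
    } else {
      muv <- pmax(sol[, "I"], 0) + pmax(sol[, "J"], 0)
      ipk <- which.max(muv)
      d <- sol[ipk, "time"] - pk_data
      A <- ypk / max(muv[ipk], 1e-8)
    }
    r0 <- exp(runif(1, log(config$r_range[1]), log(config$r_range[2])))
    out[s, ] <- c(log(A), log(r0), d, log(I0), log(rates))
  }
  out
}

nm <- function(par, fn, maxit, cycles = 1L) {
  # re-initialising the simplex at the incumbent lets Nelder-Mead escape
  # the degenerate simplexes it collapses into in 6-15 dimensions
  o <- stats::optim(par, fn, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-10))
  while (cycles > 1L) {
    cycles <- cycles - 1L
    o2 <- stats::optim(o$par, fn, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-10))
    improved <- o2$value < o$value - 1e-10
    if (o2$value <= o$value) o <- o2
    if (!improved) break
  }
  o
}

# alternate quasi-Newton (finite-difference BFGS) and Nelder-Mead rounds
# from an incumbent until neither improves; the likelihood surface is smooth
# in the log-transformed parameters, so BFGS closes the last log-units that
# a collapsed simplex leaves behind
polish_hybrid <- function(par, fn, maxit, rounds = 3L) {
  best <- list(par = par, value = fn(par), convergence = 0L)
  for (i in seq_len(rounds)) {
    v_in <- best$value
    ob <- tryCatch(
      stats::optim(best$par, fn, method = "BFGS",
                   control = list(maxit = 80L, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(ob) && ob$value < best$value)
      best <- list(par = ob$par, value = ob$value, convergence = ob$convergence)
    on <- stats::optim(best$par, fn, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-10))
    if (on$value < best$value)
      best <- list(par = on$par, value = on$value, convergence = on$convergence)
    if (v_in - best$value < 1e-4) break
  }
  best
}

# re-optimise the incumbent at the full solver tolerance and report the
# log-likelihood on that scale
final_polish <- function(best, fn_full, maxit = 150L) {
  if (!is.finite(best$value) || is.null(best$par)) return(best)
  v0 <- -fn_full(best$par)
  o <- polish_hybrid(best$par, fn_full, maxit, rounds = 2L)
  if (-o$value >= v0)
    utils::modifyList(best, list(value = -o$value, par = o$par,
                                 convergence = o$convergence))
  else
    utils::modifyList(best, list(value = v0))
}

# participating fractions at the mid-rise point of the incumbent fit's
# trajectory, where the adoption force is expressed
rise_state <- function(best, config, T_) {
  sol <- tryCatch(
    cpp_solve(1L, exp(best$par[5:6]), best$taus, config$C,
              exp(best$par[4]), 2 * T_, 0.5, 1e-6),
    error = function(e) NULL)
  if (is.null(sol)) return(c(i = 0.05, j = 0.05))
  muv <- pmax(sol[, "I"], 0) + pmax(sol[, "J"], 0)
  pk <- which.max(muv)
  half <- which(muv[seq_len(pk)] >= 0.5 * muv[pk])[1]
  c(i = max(sol[half, "I"], 1e-6), j = max(sol[half, "J"], 0))
}

fit_complex_single <- function(y, config) {
  grid <- expand.grid(tau_i = config$tau_grid, tau_j = config$tau_grid,
                      tau_r = config$tau_grid)
  ncell <- nrow(grid)
  n_probe <- config$coarse_probes
  coarse_val <- rep(-Inf, ncell)
  coarse_par <- vector("list", ncell)
  n_starts <- 0L
  rtol_s <- config$search_rtol

  # coarse pass: seeded aligned probe points in every threshold cell
  for (g in seq_len(ncell)) {
    taus <- as.integer(grid[g, ])
    fn <- obj_single("complex", taus, y, config, rtol = rtol_s)
    starts <- draw_starts(n_probe, "complex", taus, y, config)
    vals <- apply(starts, 1, fn)
    b <- which.min(vals)
    coarse_val[g] <- -vals[b]
    coarse_par[[g]] <- starts[b, ]
  }

  # refine surviving cells in descending coarse order
  ord <- order(coarse_val, decreasing = TRUE)
  best_ll <- -Inf
  ref_val <- rep(-Inf, ncell)
  ref_par <- vector("list", ncell)
  refined <- integer(0)
  for (g in ord[seq_len(min(config$refine_max, ncell))]) {
    if (coarse_val[g] < best_ll - config$prune_margin) break
    taus <- as.integer(grid[g, ])
    fn <- obj_single("complex", taus, y, config, rtol = rtol_s)
    o <- nm(coarse_par[[g]], fn, config$refine_maxit)
    n_starts <- n_starts + 1L
    ref_val[g] <- -o$value
    ref_par[[g]] <- o$par
    refined <- c(refined, g)
    if (ref_val[g] > best_ll) best_ll <- ref_val[g]
  }

  # polish the best refined cells with longer runs plus fresh restarts
  top <- refined[order(ref_val[refined], decreasing = TRUE)]
  top <- head(top, config$polish_top)
  best <- list(value = -Inf)
  for (g in top) {
    taus <- as.integer(grid[g, ])
    fn <- obj_single("complex", taus, y, config, rtol = rtol_s)
    extra <- min(max(0L, config$n_restarts - n_probe - 1L), 1L)
    starts <- rbind(matrix(ref_par[[g]], nrow = 1),
                    draw_starts(extra, "complex", taus, y, config))
    for (s in seq_len(nrow(starts))) {
      o <- nm(starts[s, ], fn, config$refine_maxit)
      o <- polish_hybrid(o$par, fn, config$polish_maxit, rounds = 2L)
      n_starts <- n_starts + 1L
      if (-o$value > best$value)
        best <- list(value = -o$value, par = o$par, taus = taus,
                     convergence = o$convergence)
    }
  }
  # Coordinate descent over the threshold grid from the polished incumbent.
  # The rate scale and the adoption thresholds trade off along a long ridge
  # (a larger threshold with a larger beta produces a similar take-off), so
  # each candidate cell is warm-started from the incumbent's continuous
  # parameters with beta rescaled by the ratio of adoption tail
  # probabilities at a characteristic mid-rise state. This walks reliably
  # between basins that cold probes score far below their refined value.
  T_ <- length(y)
  sweeps_left <- config$tau_sweeps
  while (sweeps_left > 0L) {
    sweeps_left <- sweeps_left - 1L
    moved <- FALSE
    ref <- rise_state(best, config, T_)
    f_inc <- cpp_multi_tail(ref["i"], ref["j"], config$C,
                            best$taus[1], best$taus[2])
    for (d in 1:3) {
      for (v in config$tau_grid) {
        if (v == best$taus[d]) next
        cand_taus <- best$taus
        cand_taus[d] <- v
        start <- best$par
        if (d <= 2) {
          f_cand <- cpp_multi_tail(ref["i"], ref["j"], config$C,
                                   cand_taus[1], cand_taus[2])
          if (f_cand < 1e-280) next
          start[5] <- start[5] + log(max(f_inc, 1e-280)) - log(f_cand)
          if (start[5] > log(150)) next  # ridge leaves the admissible range
        }
        fn <- obj_single("complex", cand_taus, y, config, rtol = rtol_s)
        o <- nm(start, fn, config$refine_maxit)
        n_starts <- n_starts + 1L
        if (-o$value > best$value - 10) {
          o <- polish_hybrid(o$par, fn, config$polish_maxit, rounds = 1L)
          if (-o$value > best$value + 1e-6) {
            best <- list(value = -o$value, par = o$par, taus = cand_taus,
                         convergence = best$convergence)
            moved <- TRUE
          }
        }
      }
    }
    if (!moved) break
  }

  best <- final_polish(best, obj_single("complex", best$taus, y, config))
  best$n_starts <- n_starts + 1L
  best
}

fit_simple_single <- function(y, config) {
  rtol_s <- config$search_rtol
  fn <- obj_single("simple", integer(0), y, config, rtol = rtol_s)
  starts <- draw_starts(config$n_restarts, "simple", integer(0), y, config)
  vals <- apply(starts, 1, fn)
  keep <- order(vals)[seq_len(min(5L, nrow(starts)))]
  n_starts <- 0L
  ref <- list()
  for (s in keep) {
    o <- nm(starts[s, ], fn, config$refine_maxit)
    n_starts <- n_starts + 1L
    ref[[length(ref) + 1]] <- o
  }
  ref <- ref[order(vapply(ref, `[[`, numeric(1), "value"))]
  best <- list(value = -Inf)
  for (o0 in ref[seq_len(min(3L, length(ref)))]) {
    o <- polish_hybrid(o0$par, fn, config$polish_maxit)
    n_starts <- n_starts + 1L
    if (-o$value > best$value)
      best <- list(value = -o$value, par = o$par, convergence = o$convergence)
  }
  best <- final_polish(best, obj_single("simple", integer(0), y, config))
  best$n_starts <- n_starts + 1L
  best
}

theta_from_par <- function(mechanism, par, taus = NULL) {
  if (mechanism == "complex") {
    c(A = exp(par[1]), r = exp(par[2]), delta_t = par[3], I0 = exp(par[4]),
      beta = exp(par[5]), tau_i = taus[1], tau_j = taus[2], tau_r = taus[3],
      epsilon = exp(par[6]))
  } else {
    c(A = exp(par[1]), r = exp(par[2]), delta_t = par[3], I0 = exp(par[4]),
      beta_i = exp(par[5]), beta_j = exp(par[6]), gamma = exp(par[7]),
      epsilon = exp(par[8]))
  }
}

new_fad_fit <- function(mechanism, n_subpops, theta, taus, C, log_lik, k,
                        converged, n_restarts_used, series, config) {
  structure(list(
    mechanism = mechanism, n_subpops = n_subpops, theta = theta,
    taus = taus, C = C, log_lik = log_lik, k = k, aic = 2 * k - 2 * log_lik,
    converged = converged, n_restarts_used = n_restarts_used,
    series = series, config = config), class = "fad_fit")
}

#' Fit a contagion model to a weekly interest series by maximum likelihood
#'
#' Maximises the Gamma observation likelihood over the full parameter set:
#' the dynamical parameters of the chosen mechanism, the initial fraction
#' `I0`, and the observation nuisances `(A, delta_t, r)`. For the complex
#' mechanism the integer thresholds are searched over an exhaustive grid
#' (with pruning) and the continuous parameters by derivative-free
#' optimisation within each cell; for the simple mechanism a single
#' multi-restart derivative-free search is used. `n_subpops = 2` fits the
#' two-sub-population superposition for bimodal series (independent
#' continuous parameters per sub-population, shared Gamma shape and - for
#' the complex mechanism - shared thresholds).
#'
#' Free-parameter counts: 9 (complex, single population), 8 (simple,
#' single), 14 (complex, two populations), 15 (simple, two).
#'
#' @param series a `trend_series`, data frame with a `value` column, or
#'   numeric vector.
#' @param mechanism `"complex"` or `"simple"`.
#' @param n_subpops 1 or 2.
#' @param config a [fit_config()].
#' @param single_fit optional previously computed single-population
#'   `fad_fit` of the same mechanism, used to initialise a two-population
#'   fit (computed internally when absent).
#' @return A `fad_fit` object with elements `theta`, `log_lik`, `k`,
#'   `aic`, `converged`, `n_restarts_used`. Failed optimisation is
#'   reported through `converged = FALSE`, never as an error.
#' @seealso [compare_contagion()], [tidy.fad_fit()], [glance.fad_fit()]
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_trend(simple_params(1.5, 0.5, 0.4, 0.7, I0 = 0.005),
#'                       obs_params(A = 150, r = 100), n_weeks = 40, seed = 1)
#' fit <- fit_fad(sim, "simple", config = fit_config(seed = 1))
#' glance(fit)
#' }
fit_fad <- function(series, mechanism = c("complex", "simple"), n_subpops = 1,
                    config = fit_config(), single_fit = NULL) {
  mechanism <- match.arg(mechanism)
  series <- as_trend_series(series)
  filt <- inclusion_filter(series)
  if (!filt && !config$allow_short)
    abort(sprintf(
      "series '%s' has only %d non-zero points (need > 15); set allow_short in fit_config() to override",
      series_name(series), attr(filt, "n_nonzero")))
  y <- prepare_observations(series$value, config$zero_handling)

  if (n_subpops == 2)
    return(fit_fad_twopop(series, y, mechanism, config, single_fit))

  res <- withr::with_seed(config$seed, {
    if (mechanism == "complex") fit_complex_single(y, config)
    else fit_simple_single(y, config)
  })

  # all restarts failing shows up as a pinned penalty value, not an error
  converged <- is.finite(res$value) && res$value > -1e9
  theta <- theta_from_par(mechanism, res$par, res$taus)
  new_fad_fit(mechanism, 1L, theta, taus = res$taus, C = config$C,
              log_lik = res$value, k = if (mechanism == "complex") 9L else 8L,
              converged = converged, n_restarts_used = res$n_starts,
              series = series, config = config)
}

# dynamical/observation parameter objects from a fitted model
#' Extract fitted dynamical parameters
#'
#' @param fit a `fad_fit`.
#' @param pop sub-population index (1 or 2).
#' @return A [complex_params()] or [simple_params()] object.
#' @export
fitted_dyn_params <- function(fit, pop = 1) {
  th <- fit_pop_theta(fit, pop)
  if (fit$mechanism == "complex")
    complex_params(beta = th[["beta"]], tau_i = fit$taus[1], tau_j = fit$taus[2],
                   tau_r = fit$taus[3], epsilon = th[["epsilon"]],
                   I0 = th[["I0"]], C = fit$C)
  else
    simple_params(beta_i = th[["beta_i"]], beta_j = th[["beta_j"]],
                  gamma = th[["gamma"]], epsilon = th[["epsilon"]],
                  I0 = th[["I0"]])
}

#' Extract fitted observation parameters
#'
#' @inheritParams fitted_dyn_params
#' @return An [obs_params()] object.
#' @export
fitted_obs_params <- function(fit, pop = 1) {
  th <- fit_pop_theta(fit, pop)
  obs_params(A = th[["A"]], delta_t = th[["delta_t"]], r = fit$theta[["r"]])
}

fit_pop_theta <- function(fit, pop = 1) {
  if (fit$n_subpops == 1) {
    if (pop != 1) abort("single-population fit has no second sub-population")
    return(fit$theta)
  }
  pre <- paste0("pop", pop, "_")
  th <- fit$theta[startsWith(names(fit$theta), pre)]
  names(th) <- sub(pre, "", names(th))
  th
}

#' Fitted observation mean of a model
#'
#' @param fit a `fad_fit`.
#' @param times observation times in weeks (default the fitted series'
#'   week indices).
#' @return Numeric vector of means (floored as in the likelihood).
#' @export
fitted_mean <- function(fit, times = NULL) {
  times <- times %||% (seq_len(nrow(fit$series)) - 1)
  total <- 0
  A_tot <- 0
  for (pop in seq_len(fit$n_subpops)) {
    dyn <- fitted_dyn_params(fit, pop)
    obs <- fitted_obs_params(fit, pop)
    t_max <- max(2, max(times) + max(obs$delta_t, 0) + 1)
    traj <- solve_trajectory(dyn, t_max = t_max, dt = fit$config$dt,
                             rtol = fit$config$rtol)
    total <- total + observation_mean(traj, obs, times)
    A_tot <- A_tot + obs$A
  }
  pmax(total, fit$config$mean_floor_frac * A_tot)
}

#' @export
print.fad_fit <- function(x, ...) {
  cat(sprintf("%s contagion fit (%d sub-population%s) to '%s'\n",
              x$mechanism, x$n_subpops, if (x$n_subpops > 1) "s" else "",
              series_name(x$series)))
  cat(sprintf("  logLik = %.3f, k = %d, AIC = %.3f, converged: %s\n",
              x$log_lik, x$k, x$aic, x$converged))
  cat("  theta:", paste(names(x$theta), signif(x$theta, 4), sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.fad_fit <- function(object, ...) {
  structure(object$log_lik, df = object$k, nobs = nrow(object$series),
            class = "logLik")
}
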