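# Synthetic Google-Trends-like data: the sampling dual of the Gamma
# observation likelihood, used for every recovery and coverage study.

#' Simulate a weekly percent-of-peak interest series
#'
#' Solves the deterministic contagion model, forms the weekly observation
#' means `A * mu(t + delta_t)` for `t = 0..n_weeks-1`, draws independent
#' Gamma observations with those means and shape `r`, then (optionally)
#' rescales so the maximum is exactly 100 and rounds to integers as Trends
#' does (values below 0.5 become zero weeks). With `n_subpops = 2` the
#' observation mean is the sum of two sub-population means (shared shape;
#' shared thresholds are implied by passing `dyn2` of the same mechanism).
#'
#' @param dyn a [complex_params()] or [simple_params()] object (the
#'   mechanism is inferred from its class).
#' @param obs an [obs_params()] object.
#' @param n_weeks number of weekly observations.
#' @param n_subpops 1 or 2.
#' @param dyn2,obs2 second sub-population parameters (required when
#'   `n_subpops = 2`; `obs2$r` is ignored - the shape is shared).
#' @param seed optional integer seed; the draw is reproducible given it.
#' @param rescale_to_peak rescale so the maximum value is 100 before
#'   quantisation (the percent-of-peak convention).
#' @param quantize round to integers, turning small values into the zero
#'   weeks seen in real extracts.
#' @param start_date week-start date of week 0.
#' @param name series name.
#' @param dt,rtol solver settings.
#' @return A `trend_series` tibble; the generating truth (parameters,
#'   noiseless means, rescaling factor) is attached as attribute `truth`.
#' @export
#' @examples
#' sim <- simulate_trend(complex_params(5, 2, 2, 2, epsilon = 0.5, I0 = 0.01),
#'                       obs_params(A = 150, r = 50), n_weeks = 40, seed = 42)
#' sim$value
simulate_trend <- function(dyn, obs, n_weeks, n_subpops = 1, dyn2 = NULL,
                           obs2 = NULL, seed = NULL, rescale_to_peak = TRUE,
                           quantize = TRUE, start_date = as.Date("2013-01-06"),
                           name = "synthetic", dt = 0.1, rtol = 1e-8) {
  if (n_weeks < 1) abort("`n_weeks` must be at least 1")
  if (n_subpops == 2 && (is.null(dyn2) || is.null(obs2)))
    abort("two-sub-population simulation needs `dyn2` and `obs2`")

  times <- seq(0, n_weeks - 1)
  m <- obs_mean_from_params(dyn, obs, times, dt, rtol)
  if (n_subpops == 2)
    m <- m + obs_mean_from_params(dyn2, obs2, times, dt, rtol)
  if (max(m) < 1e-9)
    abort("degenerate generator spec: the observation mean is ~0 over the window")

  y <- {
    draw <- function() rgamma(n_weeks, shape = obs$r, scale = m / obs$r)
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  sc <- 1
  if (rescale_to_peak) {
    sc <- 100 / max(y)
    y <- y * sc
  }
  if (quantize) y <- round(y)

  out <- trend_series(y, start_date = start_date, name = name)
  attr(out, "truth") <- list(
    mechanism = mechanism_of(dyn), dyn = dyn, obs = obs,
    dyn2 = dyn2, obs2 = obs2, n_subpops = n_subpops,
    mean = m, scale = sc, seed = seed)
  out
}

obs_mean_from_params <- function(dyn, obs, times, dt = 0.1, rtol = 1e-8) {
  t_max <- max(2, max(times) + max(obs$delta_t, 0) + 1)
  traj <- solve_trajectory(dyn, t_max = t_max, dt = dt, rtol = rtol)
  observation_mean(traj, obs, times)
}

#' Generate a labelled benchmark suite of synthetic fads
#'
#' Emulates a corpus of realised fads: both mechanisms in alternation,
#' parameters drawn from documented ranges (rates log-uniform on
#' `rate_range` per week, thresholds uniform on `tau_values`, initial
#' fraction log-uniform on `I0_range`, shape drawn from `r_values`), an
#' optional fraction of bimodal series, every series passing the inclusion
#' filter (more than 15 non-zero points). Draws whose realised trajectory
#' never ignites (no interior peak, or a participating fraction below
#' `min_peak_frac`) are rejected and redrawn, since the corpus being
#' emulated consists of fads that actually happened.
#'
#' @param n_fads number of series.
#' @param seed integer seed; the suite is identical across runs given it.
#' @param n_weeks weeks per series.
#' @param r_values Gamma shapes sampled uniformly per series.
#' @param prop_bimodal fraction of series generated from two
#'   sub-populations.
#' @param rate_range,I0_range,tau_values generator parameter ranges.
#' @param min_peak_frac minimum peak participating fraction `max(mu)` for
#'   a draw to count as an ignited fad.
#' @return A list of `trend_series`, each carrying its `truth` attribute;
#'   a `labels` tibble (name, mechanism, bimodal, r) is attached as an
#'   attribute of the list.
#' @export
generate_benchmark_suite <- function(n_fads, seed = 1, n_weeks = 40,
                                     r_values = c(20, 50, 200),
                                     prop_bimodal = 0.15,
                                     rate_range = c(0.1, 10),
                                     I0_range = c(1e-5, 1e-3),
                                     tau_values = 1:4,
                                     min_peak_frac = 0.02) {
  if (n_fads < 1) abort("`n_fads` must be at least 1")
  withr::with_seed(seed, {
    mechs <- rep(c("complex", "simple"), length.out = n_fads)
    bimodal <- rep(FALSE, n_fads)
    if (prop_bimodal > 0 && n_fads >= 2) {
      n_bi <- max(0L, round(prop_bimodal * n_fads))
      if (n_bi > 0) bimodal[sample.int(n_fads, n_bi)] <- TRUE
    }
    suite <- vector("list", n_fads)
    labels <- vector("list", n_fads)
    for (i in seq_len(n_fads)) {
      nm_i <- sprintf("fad%02d", i)
      suite[[i]] <- draw_valid_fad(mechs[i], bimodal[i], n_weeks, r_values,
                                   rate_range, I0_range, tau_values,
                                   min_peak_frac, name = nm_i)
      labels[[i]] <- tibble::tibble(
        name = nm_i, mechanism = mechs[i], bimodal = bimodal[i],
        r = attr(suite[[i]], "truth")$obs$r)
    }
    attr(suite, "labels") <- dplyr::bind_rows(labels)
    suite
  })
}

draw_dyn <- function(mechanism, rate_range, I0_range, tau_values) {
  lr <- function() exp(runif(1, log(rate_range[1]), log(rate_range[2])))
  I0 <- exp(runif(1, log(I0_range[1]), log(I0_range[2])))
  if (mechanism == "complex")
    complex_params(beta = lr(), tau_i = sample(tau_values, 1),
                   tau_j = sample(tau_values, 1), tau_r = sample(tau_values, 1),
                   epsilon = lr(), I0 = I0)
  else
    simple_params(beta_i = lr(), beta_j = lr(), gamma = lr(), epsilon = lr(),
                  I0 = I0)
}

draw_valid_fad <- function(mechanism, bimodal, n_weeks, r_values, rate_range,
                           I0_range, tau_values, min_peak_frac, name,
                           max_tries = 1000) {
  times <- seq(0, n_weeks - 1)
  for (try in seq_len(max_tries)) {
    dyn <- draw_dyn(mechanism, rate_range, I0_range, tau_values)
    r <- sample(rep(r_values, 2), 1)
    obs <- obs_params(A = 200, delta_t = runif(1, 0, 2), r = r)
    dyn2 <- NULL; obs2 <- NULL
    if (bimodal) {
      dyn2 <- draw_dyn(mechanism, rate_range, I0_range, tau_values)
      if (mechanism == "complex") {
        # sub-populations share the thresholds
        dyn2$tau_i <- dyn$tau_i; dyn2$tau_j <- dyn$tau_j; dyn2$tau_r <- dyn$tau_r
      }
      obs2 <- obs_params(A = obs$A * runif(1, 0.3, 0.8),
                         delta_t = obs$delta_t - runif(1, 15, 22), r = r)
    }
    # an ignited fad: interior peak well above the starting level
    mu <- tryCatch({
      m1 <- obs_mean_from_params(dyn, obs, times) / obs$A
      if (bimodal) m1 + obs_mean_from_params(dyn2, obs2, times) / obs$A else m1
    }, error = function(e) NULL)
    if (is.null(mu)) next
    pk <- which.max(mu)
    if (pk <= 2 || pk >= n_weeks - 2) next
    if (max(mu) < min_peak_frac) next
    if (max(mu) < 5 * mu[1]) next

    sim <- simulate_trend(dyn, obs, n_weeks, n_subpops = if (bimodal) 2 else 1,
                          dyn2 = dyn2, obs2 = obs2, name = name)
    if (inclusion_filter(sim)) return(sim)
  }
  abort(sprintf("could not draw an ignited fad after %d tries (%s, bimodal=%s)",
                max_tries, mechanism, bimodal))
}

#' Write a synthetic series plus its generating truth
#'
#' Writes the Trends-dialect CSV and a JSON sidecar holding the generating
#' parameters and the rescaling factor.
#'
#' @param sim a `trend_series` with a `truth` attribute.
#' @param path CSV path; the sidecar gets the extension `.truth.json`.
#' @return The CSV path, invisibly.
#' @export
write_synthetic_fad <- function(sim, path) {
  write_trends_csv(sim, path)
  truth <- attr(sim, "truth")
  if (!is.null(truth)) {
    side <- sub("\\.csv$", "", path)
    flat <- list(
      mechanism = truth$mechanism,
      n_subpops = truth$n_subpops,
      dyn = unclass(truth$dyn), obs = unclass(truth$obs),
      dyn2 = if (!is.null(truth$dyn2)) unclass(truth$dyn2),
      obs2 = if (!is.null(truth$obs2)) unclass(truth$obs2),
      scale = truth$scale, seed = truth$seed)
    jsonlite::write_json(flat, paste0(side, ".truth.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}
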