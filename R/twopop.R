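# Two-sub-population fitting and the multimodality detector.

#' Detect a bimodal interest series
#'
#' Operationalises "more than one mode": after 3-point moving-average
#' smoothing, the series is flagged when two local maxima, each at least
#' `multimodal_prominence` of the smoothed peak, are separated by a trough
#' below `multimodal_trough` of the smaller of the two maxima.
#'
#' @param series a `trend_series` or numeric vector.
#' @param config a [fit_config()] carrying the detector settings.
#' @return `TRUE` or `FALSE`.
#' @export
is_multimodal <- function(series, config = fit_config()) {
  v <- if (is.data.frame(series)) series$value else as.numeric(series)
  if (length(v) < 5) return(FALSE)
  sm <- as.numeric(stats::filter(v, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- v[is.na(sm)]
  peaks <- find_modes(sm, config$multimodal_prominence)
  if (nrow(peaks) < 2) return(FALSE)
  for (a in seq_len(nrow(peaks) - 1)) {
    for (b in seq(a + 1, nrow(peaks))) {
      trough <- min(sm[seq(peaks$idx[a], peaks$idx[b])])
      if (trough < config$multimodal_trough * min(peaks$height[a], peaks$height[b]))
        return(TRUE)
    }
  }
  FALSE
}

# local maxima of a smoothed series above a prominence fraction of its peak
find_modes <- function(sm, prominence) {
  n <- length(sm)
  idx <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < n) sm[i + 1] else -Inf
    sm[i] >= left && sm[i] > right
  }, logical(1)))
  idx <- idx[sm[idx] >= prominence * max(sm)]
  tibble::tibble(idx = idx, height = sm[idx])
}

# ---------------------------------------------------------------------------
# two-population maximum likelihood
# x layout (complex): pop1 (logA, d, logI0, logbeta, logeps), pop2 same, logr
# x layout (simple):  pop1 (logA, d, logI0, logbi, logbj, loggam, logeps), pop2, logr
# ---------------------------------------------------------------------------

obj_twopop <- function(mechanism, taus, y, config, rtol = NULL) {
  mech <- mech_code(mechanism)
  C <- config$C
  dt <- config$dt; floor_frac <- config$mean_floor_frac
  rtol <- rtol %||% config$rtol
  cl <- censor_limit_of(y)
  yv <- as.numeric(y)
  if (mechanism == "complex") {
    function(x) {
      ll <- cpp_series_loglik2(mech, exp(x[4:5]), exp(x[9:10]), taus, C,
                               exp(x[3]), exp(x[8]), exp(x[1]), exp(x[6]),
                               x[2], x[7], exp(x[11]),
                               yv, dt, rtol, floor_frac, cl)
      if (is.finite(ll)) -ll else 1e10
    }
  } else {
    function(x) {
      ll <- cpp_series_loglik2(mech, exp(x[4:7]), exp(x[11:14]), integer(0), 0L,
                               exp(x[3]), exp(x[10]), exp(x[1]), exp(x[8]),
                               x[2], x[9], exp(x[15]),
                               yv, dt, rtol, floor_frac, cl)
      if (is.finite(ll)) -ll else 1e10
    }
  }
}

# pop block of the optimiser vector from a named theta block
pop_block <- function(mechanism, th) {
  if (mechanism == "complex")
    c(log(th[["A"]]), th[["delta_t"]], log(th[["I0"]]),
      log(max(th[["beta"]], 1e-8)), log(max(th[["epsilon"]], 1e-8)))
  else
    c(log(th[["A"]]), th[["delta_t"]], log(th[["I0"]]),
      log(max(th[["beta_i"]], 1e-8)), log(max(th[["beta_j"]], 1e-8)),
      log(max(th[["gamma"]], 1e-8)), log(max(th[["epsilon"]], 1e-8)))
}

fit_fad_twopop <- function(series, y, mechanism, config, single_fit = NULL) {
  if (is.null(single_fit) || single_fit$mechanism != mechanism ||
      single_fit$n_subpops != 1)
    single_fit <- fit_fad(series, mechanism, n_subpops = 1, config = config)

  th1 <- single_fit$theta
  b1 <- pop_block(mechanism, th1)
  logr <- log(th1[["r"]])
  T_ <- length(y)

  # second-population initial guesses from the observed mode structure
  sm <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  modes <- find_modes(sm, config$multimodal_prominence)
  fitted1 <- fitted_mean(single_fit)
  pk1 <- which.max(fitted1) - 1

  starts <- list()
  # nesting start: second population with negligible amplitude
  tiny <- b1; tiny[1] <- tiny[1] + log(1e-4)
  starts[[1]] <- c(b1, tiny, logr)
  if (nrow(modes) >= 2) {
    o <- order(modes$height, decreasing = TRUE)
    second <- modes$idx[o[2]] - 1
    b2 <- b1
    b2[2] <- b1[2] - (second - pk1)              # shift to the second mode
    b2[1] <- b1[1] + log(max(modes$height[o[2]] / modes$height[o[1]], 1e-3))
    starts[[2]] <- c(b1, b2, logr)
  }

  n_dim <- length(b1) * 2 + 1
  base <- starts[[length(starts)]]
  n_extra <- max(0L, min(config$n_restarts, 6L) - length(starts))

  run_cell <- function(taus, cell_starts) {
    fn <- obj_twopop(mechanism, taus, y, config, rtol = config$search_rtol)
    best <- list(value = -Inf)
    n_starts <- 0L
    for (s in cell_starts) {
      o <- nm(s, fn, config$polish_maxit)
      o <- polish_hybrid(o$par, fn, config$polish_maxit)
      n_starts <- n_starts + 1L
      if (-o$value > best$value)
        best <- list(value = -o$value, par = o$par, taus = taus)
    }
    best$n_starts <- n_starts
    best
  }

  res <- withr::with_seed(config$seed + 1L, {
    all_starts <- c(starts, lapply(seq_len(n_extra), function(i) {
      pert <- stats::rnorm(n_dim, 0, 0.3)
      d_idx <- c(2, 2 + length(b1))
      pert[d_idx] <- stats::rnorm(2, 0, 3)
      base + pert
    }))
    if (mechanism == "complex") {
      # shared thresholds: full restarts at the single-population optimum
      # cell, single informed start at its axis neighbours
      cells <- tau_neighbourhood(single_fit$taus, config$tau_grid)
      out <- run_cell(cells[[1]], all_starts)
      total_starts <- out$n_starts
      for (cell in cells[-1]) {
        cand <- run_cell(cell, list(base))
        total_starts <- total_starts + cand$n_starts
        if (cand$value > out$value) out <- cand
      }
      out$n_starts <- total_starts
      out
    } else {
      run_cell(integer(0), all_starts)
    }
  })
  res <- final_polish(res, obj_twopop(mechanism, res$taus, y, config),
                      maxit = 300L)

  converged <- is.finite(res$value) && res$value > -1e9
  npb <- length(b1)
  nm1 <- if (mechanism == "complex") c("A", "delta_t", "I0", "beta", "epsilon")
         else c("A", "delta_t", "I0", "beta_i", "beta_j", "gamma", "epsilon")
  log_idx <- setdiff(seq_len(npb), 2)
  unpack <- function(block) {
    v <- block; v[log_idx] <- exp(v[log_idx]); setNames(v, nm1)
  }
  th_p1 <- unpack(res$par[seq_len(npb)])
  th_p2 <- unpack(res$par[npb + seq_len(npb)])
  theta <- c(setNames(th_p1, paste0("pop1_", nm1)),
             setNames(th_p2, paste0("pop2_", nm1)),
             r = exp(res$par[2 * npb + 1]))
  taus <- if (mechanism == "complex") res$taus else NULL
  if (!is.null(taus))
    theta <- c(theta, tau_i = taus[1], tau_j = taus[2], tau_r = taus[3])
  k <- if (mechanism == "complex") 14L else 15L

  new_fad_fit(mechanism, 2L, theta, taus = taus, C = config$C,
              log_lik = res$value, k = k, converged = converged,
              n_restarts_used = res$n_starts, series = series, config = config)
}

# the incumbent threshold cell plus its axis neighbours, within the grid
tau_neighbourhood <- function(taus, tau_grid) {
  cells <- list(taus)
  for (d in 1:3) {
    for (step in c(-1L, 1L)) {
      cand <- taus
      cand[d] <- cand[d] + step
      if (cand[d] %in% tau_grid) cells <- c(cells, list(cand))
    }
  }
  unique(cells)
}
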