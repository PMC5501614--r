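# a cheap converged source fit for forecasting tests: fit the simple model
# to a low-noise synthetic fad once per session
source_fit <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      sim <- make_simple_sim(seed = 20, r = 200)
      val <<- fit_fad(sim, "simple", config = fast_config())
    }
    val
  }
})

test_that("prediction band endpoints are exact central Gamma quantiles", {
  fit <- source_fit()
  target <- make_simple_sim(seed = 21, r = 200)
  fc <- transfer_forecast(fit, target[1:12, ], horizon = 30,
                          config = fast_config())
  r <- attr(fc, "r_band")
  # df correction: 4 refit nuisances on 12 early observations
  expect_equal(r, attr(fc, "obs")$r * 8 / 12)
  expect_equal(fc$lower95, qgamma(0.025, shape = r, scale = fc$mean / r),
               tolerance = 1e-12)
  expect_equal(fc$upper95, qgamma(0.975, shape = r, scale = fc$mean / r),
               tolerance = 1e-12)
  expect_true(all(fc$lower95 < fc$mean & fc$mean < fc$upper95))
})

test_that("the band collapses onto the mean as the shape grows", {
  # degenerate Gamma: with shape -> infinity the central interval width
  # shrinks to zero around the mean
  m <- c(5, 50, 100)
  for (r in c(1e4, 1e6)) {
    w <- qgamma(0.975, r, scale = m / r) - qgamma(0.025, r, scale = m / r)
    expect_lt(max(w / m), 4.2 / sqrt(r))
  }
})

test_that("a calendar shift of the target changes only the fitted time shift", {
  fit <- source_fit()
  dyn <- fitted_dyn_params(fit)
  obs <- fitted_obs_params(fit)
  base <- simulate_trend(dyn, obs_params(obs$A, obs$delta_t, 200), 12,
                         seed = 31, rescale_to_peak = FALSE)
  late <- simulate_trend(dyn, obs_params(obs$A, obs$delta_t - 2, 200), 14,
                         seed = 32, rescale_to_peak = FALSE)
  fc_base <- transfer_forecast(fit, base, horizon = 30, config = fast_config())
  fc_late <- transfer_forecast(fit, late, horizon = 32, config = fast_config())
  # the time shift and initial fraction trade off along a ridge, so the
  # identified quantity is the forecast curve's position, not delta_t alone
  pk <- peak_report(fc_base); pk_late <- peak_report(fc_late)
  expect_equal(pk_late$peak_week - pk$peak_week, 2, tolerance = 1)
  expect_equal(pk_late$duration_above_half_peak, pk$duration_above_half_peak,
               tolerance = 1)
})

test_that("peak report: triangular mean, monotone errors, degenerate input", {
  tri <- tibble::tibble(week = 0:20,
                        mean = pmax(0, 10 - 2.5 * abs(0:20 - 10)))
  # mean >= half peak (5) on weeks 8..12, with rounding the run is 5 wide;
  # build an explicit 6-week half-peak plateau instead
  m <- c(0, 1, 2, 4, 6, 6, 9, 6, 6, 5, 1, 0)
  fcst <- tibble::tibble(week = seq_along(m) - 1, mean = m)
  rep <- peak_report(fcst)
  expect_equal(rep$peak_week, 6)
  expect_equal(rep$duration_above_half_peak, 6)

  expect_error(peak_report(tibble::tibble(week = 0:5, mean = rep(0, 6))),
               "interior peak")
  expect_error(peak_report(tibble::tibble(week = 0:5, mean = 0:5)),
               "interior peak")
})

test_that("forecast preconditions are enforced", {
  fit <- source_fit()
  expect_error(transfer_forecast(fit, trend_series(c(0, 0, 5, 0)), 10),
               "3 non-zero")
})
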