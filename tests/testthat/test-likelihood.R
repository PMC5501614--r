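test_that("gamma log-likelihood reduces to known special cases", {
  # shape 1 is the exponential density with the same mean
  y <- c(3, 8, 1.5); m <- c(4, 7, 2)
  expect_equal(gamma_loglik(y, m, r = 1),
               sum(dexp(y, rate = 1 / m, log = TRUE)), tolerance = 1e-12)

  # single observation at the mean, cross-checked against stats::dgamma
  expect_equal(gamma_loglik(5, 5, r = 37),
               dgamma(5, shape = 37, scale = 5 / 37, log = TRUE),
               tolerance = 1e-12)

  # scale family: scaling data and means by c shifts the log-likelihood
  # by -T log c
  set.seed(1)
  y <- rgamma(12, 5, 1); m <- runif(12, 2, 8); cc <- 3.7
  expect_equal(gamma_loglik(cc * y, cc * m, r = 5),
               gamma_loglik(y, m, r = 5) - 12 * log(cc), tolerance = 1e-10)
})

test_that("gamma log-likelihood matches the written-out log-Gamma formula", {
  set.seed(2)
  for (rep in 1:100) {
    y <- runif(1, 0.1, 150); m <- runif(1, 0.1, 150); r <- runif(1, 0.5, 300)
    expect_equal(gamma_loglik(y, m, r), oracle_gamma_logdens(y, m, r),
                 tolerance = 1e-10)
  }
})

test_that("likelihood input validation", {
  expect_error(gamma_loglik(c(1, 2), c(1, -1), 2), "positive")
  expect_error(gamma_loglik(c(1, 2), c(1, 2), 0), "positive")
})

test_that("zero weeks are interval-censored at half the smallest positive value", {
  v <- c(0, 2, 14, 0, 7)
  y <- fadfit:::prepare_observations(v)
  expect_equal(as.numeric(y), v)
  expect_equal(attr(y, "censor_limit"), 1)
  # integer-scale data censors at 0.5
  expect_equal(attr(fadfit:::prepare_observations(c(0, 1, 100)), "censor_limit"), 0.5)
  # a series with no zeros needs no censoring
  expect_equal(attr(fadfit:::prepare_observations(c(2, 1, 100)), "censor_limit"), 0)
  expect_error(fadfit:::prepare_observations(c(0, 0, 3)), "degenerate")

  # the optional replacement rule substitutes the limit value
  yr <- fadfit:::prepare_observations(v, "replace")
  expect_equal(as.numeric(yr), c(1, 2, 14, 1, 7))
  expect_equal(attr(yr, "censor_limit"), 0)
  expect_equal(fadfit:::replace_zero_values(v), c(1, 2, 14, 1, 7))
})

test_that("censored weeks contribute the Gamma interval probability", {
  # one zero week: total = density terms for positive weeks plus
  # log P(Y < limit) for the censored one
  ps_dyn <- c(1.5, 0.5, 1.5, 0.4)
  y <- c(0, 3, 40, 100, 55, 20, 8, 4)
  traj <- solve_trajectory(simple_params(1.5, 0.5, 1.5, 0.4, I0 = 2e-3), 10)
  m <- pmax(observation_mean(traj, obs_params(300, 0, 60), seq_along(y) - 1),
            1e-6 * 300)
  manual <- sum(dgamma(y[-1], shape = 60, scale = m[-1] / 60, log = TRUE)) +
    pgamma(1.5, shape = 60, scale = m[1] / 60, log.p = TRUE)
  got <- fadfit:::cpp_series_loglik(2L, ps_dyn, integer(0), 0L, 2e-3, 300, 0,
                                    60, y, 0.1, 1e-8, 1e-6, 1.5)
  expect_equal(got, manual, tolerance = 1e-6)
})

test_that("the compiled series log-likelihood equals the R composition", {
  # the solve -> observation mean -> floor -> Gamma density chain computed
  # with exported R functions must agree with the fused compiled path
  ps <- simple_params(1.5, 0.5, 1.5, 0.4, I0 = 2e-3)
  sim <- make_simple_sim(seed = 5)
  y <- fadfit:::replace_zero_values(sim$value)
  weeks <- seq_along(y) - 1
  obs <- obs_params(A = 160, delta_t = 0.7, r = 80)
  traj <- solve_trajectory(ps, t_max = max(weeks) + 2)
  m <- pmax(observation_mean(traj, obs, weeks), 1e-6 * obs$A)
  want <- gamma_loglik(y, m, obs$r)
  got <- fadfit:::cpp_series_loglik(2L, c(1.5, 0.5, 1.5, 0.4), integer(0), 0L,
                                    2e-3, 160, 0.7, 80, y, 0.1, 1e-8, 1e-6, 0)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("invalid parameter regions yield -Inf rather than errors", {
  y <- c(1, 5, 10)
  ll <- fadfit:::cpp_series_loglik(2L, c(1, 1, 1, 1), integer(0), 0L,
                                   1.5, 100, 0, 50, y, 0.1, 1e-8, 1e-6, 0)
  expect_identical(ll, -Inf) # I0 >= 1
  ll2 <- fadfit:::cpp_series_loglik(2L, c(-1, 1, 1, 1), integer(0), 0L,
                                    0.01, 100, 0, 50, y, 0.1, 1e-8, 1e-6, 0)
  expect_identical(ll2, -Inf) # negative rate
})
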