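test_that("with no adoption the infected fraction decays as I0 e^(-eps t)", {
  ps <- simple_params(0, 0, gamma = 0.8, epsilon = 0.6, I0 = 0.02)
  traj <- solve_trajectory(ps, t_max = 20)
  expect_equal(traj$I, 0.02 * exp(-0.6 * traj$time), tolerance = 1e-5)
  expect_equal(traj$S, rep(1 - 0.02, nrow(traj)), tolerance = 1e-10)

  pc <- complex_params(0, 2, 2, 2, epsilon = 0.6, I0 = 0.02)
  trajc <- solve_trajectory(pc, t_max = 20)
  expect_equal(trajc$I, 0.02 * exp(-0.6 * trajc$time), tolerance = 1e-5)
})

test_that("susceptibles never increase (no return to susceptibility)", {
  for (p in list(complex_params(5, 2, 2, 2, epsilon = 0.3, I0 = 0.01),
                 simple_params(2, 0.5, 0.6, 0.8, I0 = 0.005))) {
    traj <- solve_trajectory(p, t_max = 40)
    expect_true(all(diff(traj$S) <= 1e-10))
    expect_equal(rowSums(traj[, c("S", "I", "J", "R")]), rep(1, nrow(traj)),
                 tolerance = 1e-8)
  }
})

test_that("compiled solver agrees with an independent lsoda integration", {
  skip_if_not_installed("deSolve")
  pc <- complex_params(5, 2, 2, 2, epsilon = 0.3, I0 = 0.01)
  traj <- solve_trajectory(pc, t_max = 30)
  ref <- deSolve::ode(c(S = 0.99, I = 0.01, J = 0, R = 0),
                      seq(0, 30, 0.1),
                      function(t, y, p) list(as.numeric(contagion_rhs(y, pc))),
                      NULL, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(as.matrix(traj[, 2:5]) - ref[, 2:5])), 1e-6)
})

test_that("observation mean applies amplitude, shift and positivity", {
  ps <- simple_params(1.5, 0.5, 0.6, 0.8, I0 = 0.01)
  traj <- solve_trajectory(ps, t_max = 30)
  weeks <- 0:25

  # identity at A = 1, delta_t = 0
  mu <- observation_mean(traj, obs_params(A = 1, delta_t = 0, r = 1), weeks)
  grid_mu <- (pmax(traj$I, 0) + pmax(traj$J, 0))[match(weeks, traj$time)]
  expect_equal(mu, grid_mu, tolerance = 1e-12)

  # linearity in A
  expect_equal(observation_mean(traj, obs_params(A = 2, delta_t = 0, r = 1), weeks),
               2 * mu, tolerance = 1e-12)

  # a positive shift moves the peak earlier in observation index
  m0 <- observation_mean(traj, obs_params(A = 1, delta_t = 0, r = 1), weeks)
  m2 <- observation_mean(traj, obs_params(A = 1, delta_t = 2, r = 1), weeks)
  expect_equal(which.max(m2), which.max(m0) - 2)

  # strictly positive whenever I0 > 0
  expect_true(all(m0 > 0))

  # times beyond the solved horizon extend the solve instead of failing
  far <- observation_mean(traj, obs_params(A = 1, delta_t = 0, r = 1), 0:60)
  expect_length(far, 61)
})

test_that("two-population mean superposes and validates its inputs", {
  pa <- simple_params(1.5, 0.5, 0.6, 0.8, I0 = 0.01)
  pb <- simple_params(1.2, 0.3, 0.5, 0.6, I0 = 0.005)
  ta <- solve_trajectory(pa, 40); tb <- solve_trajectory(pb, 40)
  weeks <- 0:35
  oa <- obs_params(A = 100, delta_t = 0, r = 1)
  ob <- obs_params(A = 80, delta_t = -15, r = 1)

  both <- two_population_mean(ta, tb, oa, ob, weeks)
  expect_equal(both,
               observation_mean(ta, oa, weeks) + observation_mean(tb, ob, weeks),
               tolerance = 1e-12)

  # amplitude 0 is disallowed by obs_params; a negligible amplitude reduces
  # to the single-population mean
  ob0 <- obs_params(A = 1e-12, delta_t = 0, r = 1)
  expect_equal(two_population_mean(ta, tb, oa, ob0, weeks),
               observation_mean(ta, oa, weeks), tolerance = 1e-8)

  # two well-separated peaks give a bimodal mean near the component peaks
  sep <- two_population_mean(ta, tb, oa, obs_params(A = 80, delta_t = -25, r = 1),
                             0:45)
  pk_a <- which.max(observation_mean(ta, oa, 0:45))
  expect_equal(which.max(sep), pk_a)
  second <- which.max(observation_mean(tb, obs_params(A = 80, delta_t = -25, r = 1), 0:45))
  trough <- min(sep[pk_a:second])
  expect_lt(trough, 0.5 * sep[second])

  # mechanism mismatch and complex threshold mismatch are errors
  pc1 <- complex_params(5, 2, 2, 2, epsilon = 0.3, I0 = 0.01)
  pc2 <- complex_params(5, 3, 2, 2, epsilon = 0.3, I0 = 0.01)
  tc1 <- solve_trajectory(pc1, 20); tc2 <- solve_trajectory(pc2, 20)
  expect_error(two_population_mean(ta, tc1, oa, ob, weeks), "same contagion mechanism")
  expect_error(two_population_mean(tc1, tc2, oa, ob, weeks), "share the thresholds")
})

test_that("solver output is invariant under halving the grid step", {
  pc <- complex_params(5, 2, 2, 2, epsilon = 0.3, I0 = 0.01)
  t1 <- solve_trajectory(pc, t_max = 30, dt = 0.1)
  t2 <- solve_trajectory(pc, t_max = 30, dt = 0.05)
  weeks <- 0:29
  mu1 <- observation_mean(t1, obs_params(1, 0, 1), weeks)
  mu2 <- observation_mean(t2, obs_params(1, 0, 1), weeks)
  expect_lt(max(abs(mu1 - mu2) / pmax(mu2, 1e-12)), 1e-6)
})
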