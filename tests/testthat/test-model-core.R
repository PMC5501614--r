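test_that("trinomial adoption probability matches exhaustive enumeration", {
  expect_equal(multinomial_threshold_prob(0, 0, 10, 2, 2), 0)
  expect_equal(multinomial_threshold_prob(1, 0, 2, 2, 2), 1)
  expect_equal(multinomial_threshold_prob(0.2, 0.1, 3, 2, 2),
               oracle_multi_tail(0.2, 0.1, 3, 2, 2), tolerance = 1e-12)

  set.seed(42)
  for (C in c(2, 3, 5, 10)) {
    for (rep in 1:20) {
      ti <- sample.int(C, 1); tj <- sample.int(C, 1)
      u <- runif(2)
      i <- min(u) * 0.99; j <- (max(u) - min(u)) * 0.99
      expect_equal(multinomial_threshold_prob(i, j, C, ti, tj),
                   oracle_multi_tail(i, j, C, ti, tj), tolerance = 1e-12)
    }
  }
})

test_that("binomial quitting probability matches direct summation", {
  expect_equal(binomial_threshold_prob(0, 10, 4), 0)
  expect_equal(binomial_threshold_prob(1, 10, 4), 1)
  expect_equal(binomial_threshold_prob(0.3, 10, 4),
               oracle_binom_tail(0.3, 10, 4), tolerance = 1e-12)
  set.seed(7)
  for (C in c(1, 4, 10)) {
    for (tr in seq_len(C)) {
      j <- runif(1)
      expect_equal(binomial_threshold_prob(j, C, tr),
                   oracle_binom_tail(j, C, tr), tolerance = 1e-12)
    }
  }
})

test_that("tail probabilities are monotone in the participating fractions", {
  i <- seq(0, 0.6, by = 0.05)
  p <- multinomial_threshold_prob(i, 0.2, 10, 3, 2)
  expect_true(all(diff(p) >= -1e-12))
  p2 <- multinomial_threshold_prob(0.2, i, 10, 3, 2)
  expect_true(all(diff(p2) >= -1e-12))
  pb <- binomial_threshold_prob(i, 10, 4)
  expect_true(all(diff(pb) >= -1e-12))
})

test_that("unit thresholds reduce to one minus the no-contact probability", {
  set.seed(11)
  for (C in c(2, 5, 10)) {
    u <- sort(runif(2)) * 0.99
    i <- u[1]; j <- u[2] - u[1]
    expect_equal(multinomial_threshold_prob(i, j, C, 1, 1),
                 1 - (1 - i - j)^C, tolerance = 1e-12)
  }
})

test_that("argument validation rejects off-simplex fractions and bad thresholds", {
  expect_error(multinomial_threshold_prob(0.7, 0.7, 10, 2, 2), "exceed")
  expect_error(multinomial_threshold_prob(0.1, 0.1, 10, 0, 2), "1..C")
  expect_error(binomial_threshold_prob(0.5, 10, 11), "1..C")
})

test_that("both right-hand sides vanish at the fad-free state and conserve N", {
  pc <- complex_params(5, 2, 2, 2, epsilon = 0.3, I0 = 0.01)
  ps <- simple_params(1.5, 0.5, 0.4, 0.7, I0 = 0.01)
  expect_equal(unname(contagion_rhs(c(1, 0, 0, 0), pc)), rep(0, 4))
  expect_equal(unname(contagion_rhs(c(1, 0, 0, 0), ps)), rep(0, 4))

  set.seed(99)
  for (rep in 1:1000) {
    x <- as.numeric(rmultinom(1, 100, runif(4))) / 100
    expect_equal(sum(contagion_rhs(x, pc)), 0, tolerance = 1e-12)
    expect_equal(sum(contagion_rhs(x, ps)), 0, tolerance = 1e-12)
  }
})

test_that("parameter constructors enforce their invariants", {
  expect_error(complex_params(-1, 2, 2, 2, 0.5), "non-negative")
  expect_error(complex_params(1, 11, 2, 2, 0.5), "1..C")
  expect_error(complex_params(1, 2, 2, 2, 0.5, I0 = 1.5), "between 0 and 1")
  expect_error(simple_params(1, 1, -0.1, 0.5), "non-negative")
  expect_error(obs_params(A = -1, r = 10), "positive")
  expect_error(obs_params(A = 1, r = 0), "positive")
})

test_that("early growth is super-exponential (1/(1-t)) for the threshold model", {
  # canvass size 2 with both adoption thresholds at 2 makes the adoption
  # probability exactly i^2; with beta = N the unscaled count I obeys
  # dI/dt ~ I^2 while I << N, whose solution from I(0) = 1 is 1/(1-t)
  N <- 1e7
  pc <- complex_params(beta = N, tau_i = 2, tau_j = 2, tau_r = 2,
                       epsilon = 0, I0 = 1 / N, C = 2)
  traj <- solve_trajectory(pc, t_max = 0.9, dt = 0.01, rtol = 1e-10)
  I_count <- traj$I * N
  expected <- 1 / (1 - traj$time)
  expect_lt(max(abs(I_count - expected) / expected), 1e-3)
})

test_that("early growth is exponential for the mass-action model", {
  # beta_i = 1/N in count units is beta_i = 1 rescaled; from I(0) = 1 the
  # count grows as e^t while I << N
  N <- 1e7
  ps <- simple_params(beta_i = 1, beta_j = 0, gamma = 0, epsilon = 0,
                      I0 = 1 / N)
  traj <- solve_trajectory(ps, t_max = 5, dt = 0.05, rtol = 1e-10)
  I_count <- traj$I * N
  expected <- exp(traj$time)
  expect_lt(max(abs(I_count - expected) / expected), 1e-3)
})

test_that("the quadratic and linear growth limits hold for the bare ODEs", {
  skip_if_not_installed("deSolve")
  # independent mini-integrations of dI/dt = I^2 and dI/dt = I
  sq <- deSolve::ode(c(I = 1), seq(0, 0.9, 0.01),
                     function(t, y, p) list(y^2), NULL,
                     rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(sq[, "I"] - 1 / (1 - sq[, "time"])) /
                  (1 / (1 - sq[, "time"]))), 1e-6)
  ex <- deSolve::ode(c(I = 1), seq(0, 5, 0.05),
                     function(t, y, p) list(y), NULL,
                     rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(ex[, "I"] - exp(ex[, "time"])) / exp(ex[, "time"])), 1e-6)
})
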