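test_that("vanishing noise reproduces the deterministic observation mean", {
  dyn <- simple_params(1.5, 0.5, 1.5, 0.4, I0 = 2e-3)
  sim <- simulate_trend(dyn, obs_params(A = 150, r = 1e9), 40, seed = 1,
                        rescale_to_peak = FALSE, quantize = FALSE)
  m <- attr(sim, "truth")$mean
  expect_lt(max(abs(sim$value - m) / m), 1e-3)
})

test_that("percent-of-peak rescaling hits exactly 100 before quantisation", {
  dyn <- simple_params(1.5, 0.5, 1.5, 0.4, I0 = 2e-3)
  sim <- simulate_trend(dyn, obs_params(A = 150, r = 50), 40, seed = 2,
                        quantize = FALSE)
  expect_equal(max(sim$value), 100)
  simq <- simulate_trend(dyn, obs_params(A = 150, r = 50), 40, seed = 2)
  expect_true(all(simq$value == round(simq$value)))
  expect_equal(max(simq$value), 100)
})

test_that("draws are seed-reproducible and Gamma-distributed around the mean", {
  dyn <- simple_params(1.5, 0.5, 1.5, 0.4, I0 = 2e-3)
  s1 <- simulate_trend(dyn, obs_params(A = 150, r = 50), 40, seed = 5)
  s2 <- simulate_trend(dyn, obs_params(A = 150, r = 50), 40, seed = 5)
  expect_identical(s1$value, s2$value)

  # Monte Carlo check of the sampler at one week: mean of many draws
  # approaches A mu within 3 standard errors
  r <- 50
  draws <- vapply(1:1000, function(s) {
    simulate_trend(dyn, obs_params(A = 150, r = r), 12, seed = s,
                   rescale_to_peak = FALSE, quantize = FALSE)$value[10]
  }, numeric(1))
  m10 <- attr(simulate_trend(dyn, obs_params(A = 150, r = r), 12, seed = 1,
                             rescale_to_peak = FALSE, quantize = FALSE),
              "truth")$mean[10]
  se <- m10 / sqrt(r) / sqrt(1000)
  expect_lt(abs(mean(draws) - m10), 3 * se)
})

test_that("degenerate generator specs are refused", {
  dyn <- simple_params(0, 0, gamma = 5, epsilon = 5, I0 = 1e-9)
  expect_error(simulate_trend(dyn, obs_params(A = 1e-6, r = 50), 10, seed = 1),
               "degenerate")
})

test_that("two-subpopulation generation needs both parameter sets", {
  dyn <- simple_params(1.5, 0.5, 1.5, 0.4, I0 = 2e-3)
  expect_error(simulate_trend(dyn, obs_params(A = 100, r = 50), 40,
                              n_subpops = 2, seed = 1), "dyn2")
})

test_that("benchmark suite: size, filter, labels, determinism", {
  suite <- generate_benchmark_suite(8, seed = 3, prop_bimodal = 0.25)
  expect_length(suite, 8)
  expect_true(all(vapply(suite, inclusion_filter, logical(1))))
  labs <- attr(suite, "labels")
  expect_equal(nrow(labs), 8)
  expect_setequal(unique(labs$mechanism), c("complex", "simple"))
  expect_equal(sum(labs$bimodal), 2)

  suite2 <- generate_benchmark_suite(8, seed = 3, prop_bimodal = 0.25)
  for (i in seq_along(suite))
    expect_identical(suite[[i]]$value, suite2[[i]]$value)
})

test_that("generated data are more likely under the generating parameters than under doubled rates", {
  # sampling-dual check: the average log-likelihood at the truth beats a
  # 2x-rates perturbation in nearly every replicate
  dyn <- simple_params(1.5, 0.5, 1.5, 0.4, I0 = 2e-3)
  obs <- obs_params(A = 150, r = 50)
  wins <- vapply(1:100, function(seed) {
    sim <- simulate_trend(dyn, obs, 40, seed = seed,
                          rescale_to_peak = FALSE, quantize = FALSE)
    y <- sim$value
    ll_true <- fadfit:::cpp_series_loglik(2L, c(1.5, 0.5, 1.5, 0.4), integer(0),
                                          0L, 2e-3, 150, 0, 50, y, 0.1, 1e-8, 1e-6, 0)
    ll_pert <- fadfit:::cpp_series_loglik(2L, 2 * c(1.5, 0.5, 1.5, 0.4), integer(0),
                                          0L, 2e-3, 150, 0, 50, y, 0.1, 1e-8, 1e-6, 0)
    ll_true > ll_pert
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
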