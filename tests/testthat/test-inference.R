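test_that("free-parameter counts match the model definitions", {
  sim <- make_simple_sim(seed = 1)
  fs <- fit_fad(sim, "simple", config = fast_config())
  fc <- fit_fad(sim, "complex", config = fast_config())
  expect_equal(fs$k, 8L)
  expect_equal(fc$k, 9L)
  expect_length(fs$theta, 8L)
  expect_length(fc$theta, 9L)
  expect_named(fc$theta, c("A", "r", "delta_t", "I0", "beta", "tau_i",
                           "tau_j", "tau_r", "epsilon"))
})

test_that("AIC identities hold exactly and via the stats generic", {
  sim <- make_simple_sim(seed = 1)
  f <- fit_fad(sim, "simple", config = fast_config())
  expect_identical(f$aic, 2 * f$k - 2 * f$log_lik)
  expect_equal(AIC(f), f$aic)
  expect_equal(as.numeric(logLik(f)), f$log_lik)
  expect_equal(attr(logLik(f), "df"), f$k)
})

test_that("fits are reproducible given the config seed", {
  sim <- make_simple_sim(seed = 2)
  f1 <- fit_fad(sim, "simple", config = fast_config(seed = 7))
  f2 <- fit_fad(sim, "simple", config = fast_config(seed = 7))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$log_lik, f2$log_lik)
})

test_that("the inclusion filter gates fitting unless overridden", {
  short <- trend_series(c(rep(0, 30), 40, 100, 30, 10, 5, 2))
  expect_error(fit_fad(short, "simple"), "non-zero")
  f <- fit_fad(short, "simple", config = fast_config(allow_short = TRUE))
  expect_s3_class(f, "fad_fit")
  expect_error(fit_fad(trend_series(c(0, 0, 5, rep(0, 10))), "simple",
                       config = fast_config(allow_short = TRUE)),
               "degenerate")
})

test_that("refitting a model's own noiseless mean cannot beat the MLE", {
  sim <- make_simple_sim(seed = 3, r = 100)
  fit <- fit_fad(sim, "simple", config = fast_config())
  # build the noiseless series implied by the fitted parameters
  m <- fitted_mean(fit)
  noiseless <- trend_series(m, name = "self")
  refit <- fit_fad(noiseless, "simple", config = fast_config(allow_short = TRUE))
  th <- fit$theta
  ll_gen <- fadfit:::cpp_series_loglik(
    2L, c(th[["beta_i"]], th[["beta_j"]], th[["gamma"]], th[["epsilon"]]),
    integer(0), 0L, th[["I0"]], th[["A"]], th[["delta_t"]], th[["r"]],
    fadfit:::replace_zero_values(noiseless$value), 0.1, 1e-8, 1e-6, 0)
  expect_gte(refit$log_lik, ll_gen - 1e-3)
})

test_that("evidence grading follows the AIC-difference boundaries", {
  expect_equal(evidence_grade(c(15, 10, 7, 6, 3, 2, 1.9, 0, -1.9, -2, -8)),
               c("***", "***", "**", "**", "*", "*", ".", ".", ".", "-", "-"))
  # identical log-likelihoods: the complex model pays one extra parameter,
  # delta AIC = -2, below positive evidence either way
  k_c <- 9; k_s <- 8; ll <- -100
  d <- (2 * k_s - 2 * ll) - (2 * k_c - 2 * ll)
  expect_equal(d, -2)
  expect_true(evidence_grade(d) %in% c(".", "-"))
})

test_that("the multimodality detector distinguishes one peak from two", {
  uni <- make_simple_sim(seed = 4)
  expect_false(is_multimodal(uni))

  dyn <- simple_params(1.5, 0.5, 1.5, 0.4, I0 = 2e-3)
  bi <- simulate_trend(dyn, obs_params(A = 150, delta_t = 0, r = 100), 55,
                       n_subpops = 2,
                       dyn2 = simple_params(1.8, 0.4, 1.2, 0.5, I0 = 2e-3),
                       obs2 = obs_params(A = 100, delta_t = -22, r = 100),
                       seed = 5)
  expect_true(is_multimodal(bi))
  # a monotone ramp has no second mode
  expect_false(is_multimodal(trend_series(seq(1, 100, length.out = 30))))
})

test_that("two-population fits nest the single-population fit and are preferred only for bimodal series", {
  cfg <- fast_config()
  dyn <- simple_params(1.5, 0.5, 1.5, 0.4, I0 = 2e-3)
  bi <- simulate_trend(dyn, obs_params(A = 150, delta_t = 0, r = 100), 55,
                       n_subpops = 2,
                       dyn2 = simple_params(1.8, 0.4, 1.2, 0.5, I0 = 2e-3),
                       obs2 = obs_params(A = 100, delta_t = -22, r = 100),
                       seed = 6)
  f1 <- fit_fad(bi, "simple", config = cfg)
  f2 <- fit_fad(bi, "simple", n_subpops = 2, config = cfg, single_fit = f1)
  expect_equal(f2$k, 15L)
  expect_gte(f2$log_lik, f1$log_lik - 1e-4)   # nesting
  expect_lt(f2$aic, f1$aic)                   # two peaks need two populations

  uni <- make_simple_sim(seed = 7, r = 100)
  u1 <- fit_fad(uni, "simple", config = cfg)
  u2 <- fit_fad(uni, "simple", n_subpops = 2, config = cfg, single_fit = u1)
  expect_gte(u2$log_lik, u1$log_lik - 1e-4)
  expect_lt(u1$aic, u2$aic)                   # one population wins on AIC
})

test_that("tidy and glance return the documented broom-style shapes", {
  sim <- make_simple_sim(seed = 8)
  f <- fit_fad(sim, "simple", config = fast_config())
  td <- tidy(f)
  expect_named(td, c("term", "population", "estimate"))
  expect_equal(nrow(td), 8)
  gl <- glance(f)
  expect_equal(gl$k, 8L)
  expect_true(gl$converged)
})
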