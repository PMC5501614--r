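# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the package implementation.

# two-part trinomial tail by exhaustive enumeration over the simplex
oracle_multi_tail <- function(i, j, C, ti, tj) {
  tot <- 0
  for (k in 0:C) {
    for (l in 0:(C - k)) {
      if (k >= ti || l >= tj) {
        coef <- factorial(C) / (factorial(k) * factorial(l) * factorial(C - k - l))
        tot <- tot + coef * i^k * j^l * (1 - i - j)^(C - k - l)
      }
    }
  }
  tot
}

# binomial upper tail by direct summation of point masses
oracle_binom_tail <- function(j, C, tr) {
  sum(vapply(tr:C, function(yy) choose(C, yy) * j^yy * (1 - j)^(C - yy),
             numeric(1)))
}

# Gamma log-density in the mean-shape parameterisation with the log-Gamma
# terms written out
oracle_gamma_logdens <- function(y, m, r) {
  r * log(r / m) - lgamma(r) + (r - 1) * log(y) - r * y / m
}

# quick deterministic synthetic fads reused across tests
make_simple_sim <- function(seed = 1, n_weeks = 40, r = 100, quantize = TRUE) {
  simulate_trend(simple_params(1.5, 0.5, 1.5, 0.4, I0 = 2e-3),
                 obs_params(A = 150, r = r), n_weeks = n_weeks,
                 seed = seed, quantize = quantize)
}

make_complex_sim <- function(seed = 1, n_weeks = 40, r = 100, quantize = TRUE) {
  simulate_trend(complex_params(5, 2, 2, 2, epsilon = 0.3, I0 = 0.01),
                 obs_params(A = 150, r = r), n_weeks = n_weeks,
                 seed = seed, quantize = quantize)
}

# fast fitting configuration for structural (non-recovery) tests
fast_config <- function(seed = 1, ...) {
  fit_config(seed = seed, coarse_probes = 2L, refine_max = 8L,
             polish_top = 1L, n_restarts = 5L, refine_maxit = 150L,
             polish_maxit = 300L, ...)
}
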