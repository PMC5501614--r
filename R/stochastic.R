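#' Exact stochastic simulation of a contagion model
#'
#' Event-driven (Gillespie direct-method) simulation of the continuous-time
#' Markov chain underlying the deterministic models: adoptions S -> I at
#' rate `S * f(I/N, J/N)`, progressions I -> J at rate `epsilon * I`, and
#' quits J -> R at rate `J * g2(J/N)` (complex) or `gamma * J` (simple).
#' Waiting times are exponential in the total rate and the event is chosen
#' proportionally to its rate, so sample paths are statistically exact.
#'
#' @param initial integer counts `(S, I, J, R)`, e.g. a
#'   [compartment_state()]. The rates use fractions of `N = sum(initial)`,
#'   so the same [complex_params()] / [simple_params()] values (defined for
#'   the rescaled `N = 1` system) apply at any population size.
#' @param params a [complex_params()] or [simple_params()] object; its `I0`
#'   field is ignored (the initial state is given explicitly).
#' @param t_max simulation horizon in weeks.
#' @param seed optional integer; when supplied the run is reproducible.
#' @param n_cap refuse populations larger than this (default 1e7) to keep
#'   runs at desk scale.
#' @return A tibble of class `fad_events` with one row per event (plus the
#'   initial state): columns `time`, `S`, `I`, `J`, `R`, `event`
#'   (0 = initial, 1 = adoption, 2 = progression, 3 = quit).
#' @export
#' @examples
#' p <- simple_params(beta_i = 2, beta_j = 0.5, gamma = 0.5, epsilon = 1)
#' ev <- simulate_events(c(S = 990, I = 10, J = 0, R = 0), p, t_max = 20, seed = 1)
#' tail(ev)
simulate_events <- function(initial, params, t_max, seed = NULL, n_cap = 1e7) {
  init <- as.integer(round(as.numeric(initial)))
  if (length(init) != 4 || any(init < 0))
    abort("`initial` must be four non-negative integer counts (S, I, J, R)")
  N <- sum(init)
  if (N > n_cap)
    abort(sprintf("population size %d exceeds the cap of %g; raise `n_cap` deliberately if intended", N, n_cap))
  if (!is.finite(t_max) || t_max <= 0) abort("`t_max` must be positive")

  run <- function() {
    cpp_gillespie(mech_code(mechanism_of(params)), dyn_vec(params),
                  taus_vec(params), C_of(params), init, t_max)
  }
  m <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  out <- tibble::as_tibble(as.data.frame(m))
  out$event <- as.integer(out$event)
  class(out) <- c("fad_events", class(out))
  attr(out, "params") <- params
  attr(out, "N") <- N
  attr(out, "seed") <- seed
  attr(out, "t_max") <- t_max
  out
}

#' Summarise an ensemble of stochastic runs on a time grid
#'
#' Each run is interpolated onto the grid as a right-continuous step
#' function (the state holds between events), then the per-time mean and
#' standard deviation of each compartment are computed across runs.
#'
#' @param runs a list of `fad_events` objects (at least 2).
#' @param grid numeric vector of times within the simulated horizon.
#' @return A tibble with columns `time`, `compartment`, `mean`, `sd`.
#' @export
ensemble_summary <- function(runs, grid) {
  if (length(runs) < 2) abort("need at least 2 runs to summarise an ensemble")
  comp <- c("S", "I", "J", "R")
  # runs x grid matrix per compartment
  acc <- lapply(comp, function(cc) {
    vals <- vapply(runs, function(r) step_interp(r, grid)[, cc], numeric(length(grid)))
    tibble::tibble(time = grid, compartment = cc,
                   mean = rowMeans(vals),
                   sd = apply(vals, 1, sd))
  })
  out <- dplyr::bind_rows(acc)
  out$compartment <- factor(out$compartment, levels = comp)
  dplyr::arrange(out, .data$time, .data$compartment)
}

# right-continuous step interpolation of an event trajectory onto a grid
step_interp <- function(run, grid) {
  idx <- findInterval(grid, run$time)
  idx[idx < 1] <- 1L
  as.matrix(run[idx, c("S", "I", "J", "R")])
}

#' Stochastic-versus-deterministic consistency study
#'
#' For each population size `N`, simulates `n_runs` stochastic paths from
#' initial state `(N - round(I0 N), round(I0 N), 0, 0)`, accumulates the
#' ensemble mean of the participating fractions on a grid, and reports the
#' supremum distance between that mean (per compartment, as fractions) and
#' the ODE solution. The mean-field limit predicts this error to scale as
#' `N^(-1/2)`.
#'
#' Runs are accumulated one at a time, so memory stays flat even at large
#' `N`.
#'
#' Two error summaries are reported. `run_error` is the average over runs
#' of each single realisation's supremum deviation from the ODE - the
#' quantity the mean-field limit bounds at `O(N^(-1/2))`. `sup_error` is
#' the supremum deviation of the ensemble-mean curve itself; it mixes the
#' `O(1/N)` bias of the chain's expectation with the `O(N^(-1/2)/sqrt(runs))`
#' Monte-Carlo error of the average, so its scaling in `N` is steeper and
#' depends on the run count.
#'
#' @param params dynamical parameters (their `I0` sets the initial fraction).
#' @param n_values vector of population sizes.
#' @param n_runs runs per population size.
#' @param t_max horizon in weeks.
#' @param seed integer seed for the whole study.
#' @param dt grid step for the comparison (default 0.25).
#' @return A tibble with columns `N`, `run_error`, `sup_error`.
#' @export
stochastic_ode_error <- function(params, n_values, n_runs = 200, t_max = 10,
                                 seed = 1, dt = 0.25) {
  grid <- seq(0, t_max, by = dt)

  res <- purrr::map_dfr(seq_along(n_values), function(k) {
    N <- n_values[k]
    i0 <- max(1L, as.integer(round(params$I0 * N)))
    init <- c(N - i0, i0, 0L, 0L)
    # ODE started at the realised (rounded) initial fraction for this N,
    # solved on a grid that divides the comparison grid so every comparison
    # time is a solver node (linear interpolation at the explosive take-off
    # would otherwise contribute an N-independent error floor)
    params_n <- params
    params_n$I0 <- i0 / N
    dt_solve <- dt / max(1, ceiling(dt / 0.1))
    ode <- solve_trajectory(params_n, t_max = t_max + dt, dt = dt_solve)
    ode_m <- vapply(c("S", "I", "J", "R"), function(cc)
      stats::approx(ode$time, ode[[cc]], xout = grid)$y, numeric(length(grid)))
    tot <- matrix(0, length(grid), 4)
    run_sup <- numeric(n_runs)
    for (run in seq_len(n_runs)) {
      ev <- simulate_events(init, params, t_max = t_max,
                            seed = seed + 7919L * k + run)
      st <- step_interp(ev, grid)
      tot <- tot + st
      run_sup[run] <- max(abs(st / N - ode_m))
    }
    frac <- tot / (n_runs * N)
    tibble::tibble(N = N, run_error = mean(run_sup),
                   sup_error = max(abs(frac - ode_m)))
  })
  res
}

#' Export an event trajectory as CSV
#'
#' @param run a `fad_events` object.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_events_csv <- function(run, path) {
  write.csv(as.data.frame(run)[, c("time", "S", "I", "J", "R")], path,
            row.names = FALSE)
  invisible(path)
}
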