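# broom-style tidiers for fitted objects

#' Tidy a fitted contagion model
#'
#' @param x a `fad_fit`.
#' @param ... unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, and
#'   the sub-population (`NA` for shared parameters).
#' @method tidy fad_fit
#' @export
tidy.fad_fit <- function(x, ...) {
  nm <- names(x$theta)
  pop <- ifelse(startsWith(nm, "pop1_"), 1L,
                ifelse(startsWith(nm, "pop2_"), 2L, NA_integer_))
  if (x$n_subpops == 1) pop <- rep(1L, length(nm))
  tibble::tibble(term = sub("^pop[12]_", "", nm),
                 population = pop,
                 estimate = unname(x$theta))
}

#' Glance at a fitted contagion model
#'
#' @param x a `fad_fit`.
#' @param ... unused.
#' @return A one-row tibble: mechanism, sub-population count, logLik,
#'   parameter count, AIC, convergence flag, restarts used.
#' @method glance fad_fit
#' @export
glance.fad_fit <- function(x, ...) {
  tibble::tibble(mechanism = x$mechanism, n_subpops = x$n_subpops,
                 logLik = x$log_lik, k = x$k, AIC = x$aic,
                 converged = x$converged, n_restarts_used = x$n_restarts_used)
}

#' Tidy a model comparison
#'
#' @param x a `fad_comparison`.
#' @param ... unused.
#' @return The stacked [glance.fad_fit()] rows of the two selected fits.
#' @method tidy fad_comparison
#' @export
tidy.fad_comparison <- function(x, ...) {
  dplyr::bind_rows(glance(x$complex), glance(x$simple))
}

#' Glance at a model comparison
#'
#' @param x a `fad_comparison`.
#' @param ... unused.
#' @return A one-row tibble: `delta_loglik` (complex minus simple),
#'   `delta_aic` (simple minus complex), evidence `grade`, and the
#'   selected sub-population counts.
#' @method glance fad_comparison
#' @export
glance.fad_comparison <- function(x, ...) {
  tibble::tibble(name = x$name, delta_loglik = x$delta_loglik,
                 delta_aic = x$delta_aic, grade = x$grade,
                 complex_subpops = x$complex$n_subpops,
                 simple_subpops = x$simple$n_subpops,
                 multimodal = x$multimodal)
}

#' Serialise a fit to a one-row parameter table
#'
#' Mirrors the layout of a per-fad parameter file: one row per fad with
#' the full parameter set, a second parameter block for two-peak fits.
#'
#' @param fit a `fad_fit`.
#' @return A one-row tibble.
#' @export
fit_parameter_row <- function(fit) {
  dplyr::bind_cols(
    tibble::tibble(name = series_name(fit$series), mechanism = fit$mechanism,
                   n_subpops = fit$n_subpops, log_lik = fit$log_lik,
                   k = fit$k, aic = fit$aic, converged = fit$converged),
    tibble::as_tibble(as.list(fit$theta)))
}
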