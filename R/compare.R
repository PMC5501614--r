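#' AIC evidence grade for complex over simple contagion
#'
#' Classifies the AIC difference `delta_aic = AIC_simple - AIC_complex`
#' into grades of evidence for the complex contagion model:
#' `"***"` very strong (`delta_aic >= 10`), `"**"` strong (`>= 6`),
#' `"*"` positive (`>= 2`), `"."` no significant evidence for either model
#' (`> -2`), `"-"` strong evidence against (`<= -2`). Boundaries are
#' configurable via [fit_config()].
#'
#' @param delta_aic numeric vector of AIC differences (simple minus
#'   complex, so positive favours complex).
#' @param boundaries increasing positive boundaries for positive, strong
#'   and very strong evidence.
#' @return Character vector of grades.
#' @export
#' @examples
#' evidence_grade(c(12, 7, 3, 0.5, -4))
evidence_grade <- function(delta_aic, boundaries = c(positive = 2, strong = 6, very_strong = 10)) {
  b <- sort(as.numeric(boundaries))
  vapply(delta_aic, function(d) {
    if (d >= b[3]) "***"
    else if (d >= b[2]) "**"
    else if (d >= b[1]) "*"
    else if (d > -b[1]) "."
    else "-"
  }, character(1))
}

#' Compare complex and simple contagion fits of one series
#'
#' Fits both mechanisms by maximum likelihood. When the series is flagged
#' bimodal by [is_multimodal()] (or `config$force_two_pop` is set), the
#' two-sub-population version of each mechanism is fitted as well and the
#' sub-population count is selected per mechanism by AIC. The selected
#' fits are then compared through `delta_aic = AIC_simple - AIC_complex`
#' and graded with [evidence_grade()].
#'
#' @param series a `trend_series` (or anything [trend_series()] accepts).
#' @param config a [fit_config()].
#' @return An object of class `fad_comparison`: a list with the selected
#'   `complex` and `simple` fits, `delta_loglik` (complex minus simple),
#'   `delta_aic`, `grade`, and the multimodality flag.
#' @export
compare_contagion <- function(series, config = fit_config()) {
  series <- as_trend_series(series)
  mm <- is_multimodal(series, config) || config$force_two_pop

  select_fit <- function(mechanism) {
    f1 <- fit_fad(series, mechanism, n_subpops = 1, config = config)
    if (!mm) return(f1)
    f2 <- fit_fad(series, mechanism, n_subpops = 2, config = config,
                  single_fit = f1)
    if (f2$converged && f2$aic < f1$aic) f2 else f1
  }

  fc <- select_fit("complex")
  fs <- select_fit("simple")

  delta_aic <- fs$aic - fc$aic
  structure(list(
    complex = fc, simple = fs,
    delta_loglik = fc$log_lik - fs$log_lik,
    delta_aic = delta_aic,
    grade = evidence_grade(delta_aic, config$grade_boundaries),
    multimodal = mm,
    name = series_name(series)), class = "fad_comparison")
}

#' @export
print.fad_comparison <- function(x, ...) {
  cat(sprintf("Contagion model comparison for '%s'\n", x$name))
  cat(sprintf("  complex: logLik %.2f (k=%d, %d pop), simple: logLik %.2f (k=%d, %d pop)\n",
              x$complex$log_lik, x$complex$k, x$complex$n_subpops,
              x$simple$log_lik, x$simple$k, x$simple$n_subpops))
  cat(sprintf("  delta logLik = %.2f, delta AIC = %.2f, grade: %s\n",
              x$delta_loglik, x$delta_aic, x$grade))
  invisible(x)
}
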