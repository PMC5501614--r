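# ggplot2 autoplot methods

#' Plot a weekly interest series
#'
#' @param object a `trend_series`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot trend_series
#' @export
autoplot.trend_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_col(fill = "grey65", width = 6) +
    ggplot2::labs(x = NULL, y = "Interest (% of peak)",
                  title = series_name(object)) +
    ggplot2::theme_minimal()
}

#' Plot a solved model trajectory
#'
#' @param object a `fad_trajectory`.
#' @param ... unused.
#' @return A ggplot with one line per compartment.
#' @method autoplot fad_trajectory
#' @export
autoplot.fad_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), cols = c("S", "I", "J", "R"),
                              names_to = "compartment", values_to = "fraction")
  long$compartment <- factor(long$compartment, levels = c("S", "I", "J", "R"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$fraction,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (weeks)", y = "Population fraction") +
    ggplot2::theme_minimal()
}

#' Plot a fitted model against its data
#'
#' @param object a `fad_fit`.
#' @param ... unused.
#' @return A ggplot with observed points and the fitted weekly mean.
#' @method autoplot fad_fit
#' @export
autoplot.fad_fit <- function(object, ...) {
  weeks <- seq_len(nrow(object$series)) - 1
  df <- tibble::tibble(week = weeks, observed = object$series$value,
                       fitted = fitted_mean(object, weeks))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$week)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#d1495b",
                       linewidth = 0.8) +
    ggplot2::labs(x = "Week", y = "Interest (% of peak)",
                  title = sprintf("%s contagion fit: %s", object$mechanism,
                                  series_name(object$series)),
                  subtitle = sprintf("logLik %.1f, AIC %.1f", object$log_lik,
                                     object$aic)) +
    ggplot2::theme_minimal()
}

#' Plot a forecast with its 95% prediction band
#'
#' @param object a `fad_forecast`.
#' @param ... unused.
#' @return A ggplot showing the band, the forecast mean and the early
#'   observations the nuisances were refit on.
#' @method autoplot fad_forecast
#' @export
autoplot.fad_forecast <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$week)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95, ymax = .data$upper95),
                         fill = "#66a182", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "#2e4057") +
    ggplot2::labs(x = "Week", y = "Interest (% of peak)",
                  title = "Transfer forecast with 95% prediction interval") +
    ggplot2::theme_minimal()
  early <- attr(object, "target_early")
  if (!is.null(early)) {
    df <- tibble::tibble(week = seq_len(nrow(early)) - 1, value = early$value)
    p <- p + ggplot2::geom_point(data = df,
                                 ggplot2::aes(x = .data$week, y = .data$value),
                                 colour = "grey30")
  }
  p
}

#' Plot a comparison of both mechanisms on one series
#'
#' @param object a `fad_comparison`.
#' @param ... unused.
#' @return A ggplot overlaying both fitted means on the data.
#' @method autoplot fad_comparison
#' @export
autoplot.fad_comparison <- function(object, ...) {
  weeks <- seq_len(nrow(object$complex$series)) - 1
  df <- tibble::tibble(
    week = rep(weeks, 2),
    fitted = c(fitted_mean(object$complex, weeks),
               fitted_mean(object$simple, weeks)),
    mechanism = rep(c("complex", "simple"), each = length(weeks)))
  obs <- tibble::tibble(week = weeks, value = object$complex$series$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$week)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$value), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted, colour = .data$mechanism),
                       linewidth = 0.8) +
    ggplot2::labs(x = "Week", y = "Interest (% of peak)",
                  title = sprintf("%s: delta AIC %.1f (%s)", object$name,
                                  object$delta_aic, object$grade)) +
    ggplot2::theme_minimal()
}
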