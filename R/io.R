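#' Construct a weekly percent-of-peak interest series
#'
#' The container used throughout the package for weekly search-interest
#' data: one row per week with the week-start date (Sundays, the Trends
#' convention) and the interest value on the 0-100 percent-of-peak scale.
#' Model time is the week index `0..T-1`; calendar dates are metadata.
#'
#' @param values numeric vector of non-negative weekly values.
#' @param start_date week-start date of the first observation (a `Date` or
#'   ISO string). Defaults to an arbitrary Sunday.
#' @param name series name (the search term).
#' @return A tibble of class `trend_series` with columns `date`, `value`.
#' @export
#' @examples
#' trend_series(c(0, 3, 18, 100, 61, 24, 10, 4), name = "planking")
trend_series <- function(values, start_date = as.Date("2013-01-06"), name = "fad") {
  values <- as.numeric(values)
  if (length(values) < 1) abort("a series needs at least one observation")
  if (any(!is.finite(values)) || any(values < 0))
    abort("series values must be finite and non-negative")
  start_date <- as.Date(start_date)
  out <- tibble::tibble(date = start_date + 7 * (seq_along(values) - 1),
                        value = values)
  class(out) <- c("trend_series", class(out))
  attr(out, "fad_name") <- name
  out
}

as_trend_series <- function(x, name = NULL) {
  if (inherits(x, "trend_series")) return(x)
  if (is.numeric(x)) return(trend_series(x, name = name %||% "series"))
  if (is.data.frame(x)) {
    if (!all(c("value") %in% names(x)))
      abort("a series data frame needs a `value` column")
    start <- if ("date" %in% names(x)) as.Date(x$date[1]) else as.Date("2013-01-06")
    return(trend_series(x$value, start_date = start,
                        name = name %||% attr(x, "fad_name") %||% "series"))
  }
  abort("cannot interpret `series`; supply a trend_series, data frame or numeric vector")
}

series_name <- function(x) attr(x, "fad_name") %||% "series"

#' Read a Google-Trends-dialect CSV
#'
#' Accepts both the bare two-column form (ISO week-start date, value) and
#' the export form with a preamble (`Category: ...` line, blank line, then
#' a `Week,<term>` header). Cells equal to `"<1"` parse as 0. The series
#' name is taken from the header column when present, otherwise from the
#' file name.
#'
#' @param path path to the CSV file.
#' @return A `trend_series` tibble.
#' @export
read_trends_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    abort(sprintf("empty Trends file: %s", path))

  name <- sub("\\.csv$", "", basename(path))
  first_data <- 1L
  if (grepl("^Category:", lines[1])) {
    hdr <- which(grepl("^Week,", lines))
    if (length(hdr) == 0)
      abort(sprintf("malformed Trends export (no 'Week,' header): %s", path))
    name <- strsplit(lines[hdr[1]], ",", fixed = TRUE)[[1]][2] %||% name
    first_data <- hdr[1] + 1L
  } else if (grepl("^Week,", lines[1])) {
    name <- strsplit(lines[1], ",", fixed = TRUE)[[1]][2] %||% name
    first_data <- 2L
  }

  dates <- c(); vals <- c()
  for (ln in seq(first_data, length(lines))) {
    row <- trimws(lines[ln])
    if (!nzchar(row)) next
    parts <- strsplit(row, ",", fixed = TRUE)[[1]]
    d <- tryCatch(as.Date(parts[1]), error = function(e) as.Date(NA))
    if (length(parts) < 2 || is.na(d))
      abort(sprintf("malformed row at line %d of %s: '%s'", ln, path, row))
    cell <- trimws(parts[2])
    v <- if (cell == "<1") 0 else suppressWarnings(as.numeric(cell))
    if (is.na(v))
      abort(sprintf("malformed value at line %d of %s: '%s'", ln, path, cell))
    dates <- c(dates, d); vals <- c(vals, v)
  }
  if (length(vals) == 0) abort(sprintf("no data rows in %s", path))
  out <- trend_series(vals, start_date = as.Date(dates[1], origin = "1970-01-01"),
                      name = name)
  out$date <- as.Date(dates, origin = "1970-01-01")
  out
}

#' Write a series in the Google Trends export dialect
#'
#' @param series a `trend_series` (or anything [trend_series()] accepts).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trends_csv <- function(series, path) {
  series <- as_trend_series(series)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("Category: All categories", "",
               paste0("Week,", series_name(series)),
               paste(format(series$date), series$value, sep = ",")), con)
  invisible(path)
}

#' Inclusion filter for fitting
#'
#' A series is accepted for model fitting when it has more than 15
#' strictly positive weekly values; shorter signals do not identify the
#' contagion dynamics.
#'
#' @param series a `trend_series` or numeric vector.
#' @return `TRUE`/`FALSE`, with the count of non-zero points attached as
#'   attribute `n_nonzero`.
#' @export
#' @examples
#' inclusion_filter(trend_series(rep(c(10, 0), 10)))
inclusion_filter <- function(series) {
  v <- if (is.data.frame(series)) series$value else as.numeric(series)
  n <- sum(v > 0)
  structure(n > 15, n_nonzero = n)
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("Weekly interest series '%s': %d weeks, %d non-zero, peak %g\n",
              series_name(x), nrow(x), sum(x$value > 0), max(x$value)))
  NextMethod()
}
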