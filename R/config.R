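# Structured-file interfaces: fitting configuration in YAML, fit results
# as a one-row-per-fad parameter table.

#' Read a fitting configuration from a YAML file
#'
#' Any field of [fit_config()] may appear in the file; missing fields take
#' their defaults. Unknown fields are an error.
#'
#' @param path path to a YAML file.
#' @return A `fit_config` list.
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".yaml")
#' writeLines(c("seed: 7", "n_restarts: 6", "zero_handling: censor"), tmp)
#' read_fit_config(tmp)$seed
read_fit_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(fit_config)))
  if (length(unknown) > 0)
    abort(sprintf("unknown fit_config fields in %s: %s", path,
                  paste(unknown, collapse = ", ")))
  do.call(fit_config, vals)
}

#' Serialise fitted models to a parameter table
#'
#' One row per fad with the full fitted parameter set; two-population fits
#' carry their second parameter block in `pop2_*` columns. Written as CSV
#' (and optionally JSON) mirroring a per-fad parameter file.
#'
#' @param fits a `fad_fit` or list of them.
#' @param path output CSV path; a `.json` twin is written when
#'   `json = TRUE`.
#' @param json also write a JSON version.
#' @return The combined tibble, invisibly.
#' @export
write_fit_results <- function(fits, path, json = FALSE) {
  if (inherits(fits, "fad_fit")) fits <- list(fits)
  tbl <- dplyr::bind_rows(lapply(fits, fit_parameter_row))
  write.csv(tbl, path, row.names = FALSE)
  if (json)
    jsonlite::write_json(tbl, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  invisible(tbl)
}
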