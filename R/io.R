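# CSV interchange. All writers emit ISO-8601 date labels alongside the
# (year, doy) index used internally; readers accept either.

add_date_column <- function(df) {
  dplyr::mutate(df, date = iso_date(year, doy), .before = 1)
}

ensure_year_doy <- function(df) {
  if (all(c("year", "doy") %in% names(df))) {
    return(df)
  }
  if (!"date" %in% names(df)) {
    stop("need either (year, doy) or a date column", call. = FALSE)
  }
  dplyr::bind_cols(parse_iso_date(df$date), dplyr::select(df, -"date"))
}

#' Read and write the long-format CSV schemas
#'
#' `write_series_csv()`/`read_series_csv()` handle any daily table carrying
#' a `(year, doy)` (or ISO `date`) index, e.g. driver tables, flux series
#' and processed sap flow. `write_sensor_csv()`/`read_sensor_csv()` handle
#' the long sensor schema (`tree_id`, `sensor_id`, timestamp, `value`,
#' `daytime_flag`).
#'
#' @param df Table to write.
#' @param path CSV path.
#' @return Readers return a tibble with `year`/`doy` columns restored;
#'   writers return `path` invisibly.
#' @export
write_series_csv <- function(df, path) {
  readr::write_csv(add_date_column(df), path)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  ensure_year_doy(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname write_series_csv
#' @export
write_sensor_csv <- function(df, path) {
  stopifnot(all(c("tree_id", "sensor_id", "value") %in% names(df)))
  readr::write_csv(add_date_column(df), path)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_sensor_csv <- function(path) {
  out <- ensure_year_doy(readr::read_csv(path, show_col_types = FALSE))
  if (!"daytime_flag" %in% names(out)) out$daytime_flag <- TRUE
  out
}
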