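# 365-day calendar helpers.
#
# All simulated and processed series live on a fixed 365-day year (no leap
# days), indexed by integer (year, doy). This keeps day-of-year and
# week-of-year alignment across years exact, which the extreme-run and
# weekly-band computations rely on.

DAYS_PER_YEAR <- 365L

# month lengths of a non-leap year
MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_START_DOY <- c(1L, cumsum(MONTH_DAYS)[-12] + 1L)

#' Week of year on the 365-day calendar
#'
#' Weeks are consecutive 7-day blocks starting 1 January; the 52nd week
#' absorbs the remaining 8th day so every year has exactly 52 weeks.
#'
#' @param doy Integer day of year in 1..365.
#' @return Integer week of year in 1..52.
#' @export
week_of_year <- function(doy) {
  stopifnot(all(doy >= 1 & doy <= DAYS_PER_YEAR, na.rm = TRUE))
  pmin((as.integer(doy) - 1L) %/% 7L + 1L, 52L)
}

#' Month containing a day of year
#'
#' @param doy Integer day of year in 1..365.
#' @return Integer month in 1..12 (non-leap month lengths).
#' @export
month_of_doy <- function(doy) {
  stopifnot(all(doy >= 1 & doy <= DAYS_PER_YEAR, na.rm = TRUE))
  findInterval(as.integer(doy), MONTH_START_DOY)
}

#' First day of year of a month
#' @param month Integer month 1..12.
#' @return Integer day of year of the first day of that month.
#' @export
doy_of_month_start <- function(month) {
  stopifnot(all(month >= 1 & month <= 12))
  MONTH_START_DOY[as.integer(month)]
}

# all (year, doy) rows of a multi-year record
seq_days <- function(start_year, end_year) {
  years <- seq.int(start_year, end_year)
  tibble(
    year = rep(years, each = DAYS_PER_YEAR),
    doy = rep(seq_len(DAYS_PER_YEAR), length(years))
  )
}

# continuous day index from the record start (0-based), for trends/decay
day_index <- function(year, doy, origin_year) {
  (year - origin_year) * DAYS_PER_YEAR + (doy - 1L)
}

#' ISO-8601 date label for a (year, doy) pair
#'
#' Maps the 365-day calendar onto non-leap month/day labels (so 29 February
#' never occurs). Intended for CSV export and plot axes only; all
#' computations use (year, doy).
#'
#' @param year,doy Integer vectors.
#' @return Character vector of `YYYY-MM-DD` labels.
#' @export
iso_date <- function(year, doy) {
  m <- month_of_doy(doy)
  d <- as.integer(doy) - MONTH_START_DOY[m] + 1L
  sprintf("%04d-%02d-%02d", as.integer(year), m, d)
}

# inverse of iso_date(); accepts "YYYY-MM-DD", maps 29 Feb onto 28 Feb
parse_iso_date <- function(x) {
  parts <- matrix(as.integer(unlist(strsplit(x, "-", fixed = TRUE))),
    ncol = 3, byrow = TRUE
  )
  d <- pmin(parts[, 3], MONTH_DAYS[parts[, 2]])
  tibble(
    year = parts[, 1],
    doy = MONTH_START_DOY[parts[, 2]] + d - 1L
  )
}
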