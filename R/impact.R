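# Direct drought-impact statistics and record-extreme runs.

PERIOD_CHOICES <- c("full_year", "first_half", "second_half")

period_doys <- function(period) {
  jul1 <- doy_of_month_start(7L)
  switch(period,
    full_year = seq_len(DAYS_PER_YEAR),
    first_half = seq_len(jul1 - 1L),
    second_half = seq.int(jul1, DAYS_PER_YEAR)
  )
}

#' SD-scaled anomalies and rank statistics of a focal year
#'
#' For the whole year and for each half-year (split at 1 July), the focal
#' year's period mean is compared with the period means of all other years:
#' the anomaly is expressed in units of the other years' SD, and the rank
#' fraction is the share of all years (focal included, ties counted) whose
#' period mean does not exceed the focal year's.
#'
#' @param series Tibble `year`, `doy`, `value`, optionally a `variable`
#'   column (processed independently).
#' @param focal_year Year to compare (e.g. the drought year).
#' @param periods Subset of `"full_year"`, `"first_half"`, `"second_half"`.
#' @return Tibble `variable` (if present), `period`, `year_value`,
#'   `longterm_mean`, `anomaly_sd`, `rank_fraction`, `n_years`.
#' @export
period_impact <- function(series, focal_year,
                          periods = PERIOD_CHOICES) {
  periods <- match.arg(periods, PERIOD_CHOICES, several.ok = TRUE)
  stopifnot(all(c("year", "doy", "value") %in% names(series)))
  if (dplyr::n_distinct(series$year) < 3) {
    stop("need >= 3 years of data", call. = FALSE)
  }
  if (!focal_year %in% series$year) {
    stop("focal year absent from the series", call. = FALSE)
  }
  has_var <- "variable" %in% names(series)
  groups <- if (has_var) split(series, series$variable) else list(value = series)

  rows <- purrr::imap(groups, function(df, var) {
    purrr::map(periods, function(p) {
      sub <- df[df$doy %in% period_doys(p) & !is.na(df$value), ]
      means <- tapply(sub$value, sub$year, mean)
      if (!as.character(focal_year) %in% names(means)) {
        warning(sprintf(
          "no valid %s days for %s in %d; row omitted", p, var, focal_year
        ))
        return(NULL)
      }
      focal <- means[[as.character(focal_year)]]
      others <- means[names(means) != as.character(focal_year)]
      tibble(
        variable = var,
        period = p,
        year_value = focal,
        longterm_mean = mean(others),
        anomaly_sd = if (focal == mean(others)) 0 else (focal - mean(others)) / sd(others),
        rank_fraction = mean(means <= focal),
        n_years = length(means)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (!has_var) out$variable <- NULL
  out
}

#' Periods when a focal year is the pointwise record extreme
#'
#' For each day of year at which every year has a value, the focal year is a
#' pointwise minimum (maximum) if it lies strictly below (above) every other
#' year's value that day; ties yield no extreme. Maximal consecutive runs of
#' at least `min_len` days (default 8, i.e. longer than one week) are
#' reported. Days at which any year is missing are skipped and break runs.
#'
#' @param series Tibble `year`, `doy`, `value`.
#' @param focal_year Year tested for record extremes.
#' @param min_len Minimum run length in days (inclusive).
#' @return Tibble `year`, `kind` (`"min"`/`"max"`), `start_doy`, `end_doy`,
#'   `length_days`.
#' @export
extreme_runs <- function(series, focal_year, min_len = 8L) {
  stopifnot(all(c("year", "doy", "value") %in% names(series)))
  wide <- tidyr::pivot_wider(
    dplyr::select(series, year, doy, value),
    names_from = year, values_from = value
  )
  wide <- dplyr::arrange(wide, doy)
  fc <- as.character(focal_year)
  if (!fc %in% names(wide)) stop("focal year absent from the series", call. = FALSE)
  others <- setdiff(names(wide), c("doy", fc))
  om <- as.matrix(wide[, others])
  fv <- wide[[fc]]
  complete <- !is.na(fv) & rowSums(is.na(om)) == 0
  is_min <- complete & fv < apply(om, 1, min)
  is_max <- complete & fv > apply(om, 1, max)

  runs_of <- function(flag, kind) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) {
      return(NULL)
    }
    tibble(
      year = focal_year, kind = kind,
      start_doy = wide$doy[starts[keep]],
      end_doy = wide$doy[ends[keep]],
      length_days = r$lengths[keep]
    )
  }
  out <- dplyr::bind_rows(runs_of(is_min, "min"), runs_of(is_max, "max"))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(
      year = integer(), kind = character(),
      start_doy = integer(), end_doy = integer(), length_days = integer()
    ))
  }
  dplyr::arrange(out, start_doy)
}

#' Centred moving-average smoothing (presentation only)
#'
#' Centred moving average over available values, e.g. a 28-day window for
#' annual-cycle figures. Smoothing is a display aid: no statistic in the
#' package consumes smoothed series.
#'
#' @param series Tibble `year`, `doy`, `value` (ordered internally).
#' @param window Window width in days (`1` = identity).
#' @return Tibble of the same shape with smoothed `value`.
#' @export
smooth_series <- function(series, window) {
  stopifnot(window >= 1)
  if (window == 1) {
    return(series)
  }
  series <- dplyr::arrange(series, year, doy)
  series$value <- zoo::rollapply(series$value,
    width = window,
    FUN = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
    fill = NA, align = "center", partial = TRUE
  )
  series
}
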