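# Long-term sap-flow processing.
#
# Thermal-dissipation sensors lose signal strength over multi-year records
# (tree growth detaches the probe from conducting xylem) and are replaced at
# irregular dates, so raw values are not comparable across the record. The
# pipeline makes the *temporal dynamics* consistent at the cost of absolute
# interpretability: (a) daytime aggregation + availability filtering +
# annual 3-SD outlier removal, (b) removal of the low-frequency trend via a
# seasonal-trend decomposition, (c) division by a 3-year moving-window
# annual SD, (d) averaging sensors per tree. No gap-filling is performed at
# any step.

#' Aggregate half-hourly sensor records to daytime daily means
#'
#' A daily value is the mean of the available daytime half-hourly values,
#' and is only computed when at least `min_frac` (default 70%, inclusive) of
#' the day's daytime slots are available; otherwise the day is missing.
#' Daily-resolution input (no `slot` column) passes through unchanged.
#'
#' @param sensors Long sensor tibble from [simulate_sensors()] or
#'   [read_sensor_csv()]: `tree_id`, `sensor_id`, `year`, `doy`, optionally
#'   `slot`, `value`, `daytime_flag`.
#' @param min_frac Minimum available fraction of daytime slots (inclusive).
#' @return Daily tibble `tree_id`, `sensor_id`, `year`, `doy`, `value`,
#'   `stage = "aggregated"`.
#' @export
aggregate_daily <- function(sensors, min_frac = 0.7) {
  stopifnot(min_frac >= 0, min_frac <= 1)
  if (!"slot" %in% names(sensors)) {
    out <- dplyr::select(sensors, tree_id, sensor_id, year, doy, value)
  } else {
    out <- sensors %>%
      dplyr::group_by(tree_id, sensor_id, year, doy) %>%
      dplyr::summarise(
        n_daytime = sum(daytime_flag),
        n_avail = sum(daytime_flag & !is.na(value)),
        day_mean = if (sum(daytime_flag & !is.na(value)) > 0) {
          mean(value[daytime_flag], na.rm = TRUE)
        } else {
          NA_real_
        },
        .groups = "drop"
      ) %>%
      dplyr::mutate(
        value = dplyr::if_else(
          .data$n_daytime > 0 & .data$n_avail >= min_frac * .data$n_daytime,
          .data$day_mean, NA_real_
        )
      ) %>%
      dplyr::select(tree_id, sensor_id, year, doy, value)
  }
  dplyr::mutate(dplyr::arrange(out, tree_id, sensor_id, year, doy),
    stage = "aggregated"
  )
}

#' Drop calendar years with insufficient daily coverage
#'
#' A calendar year of a sensor is retained only if at least `min_frac`
#' (default 40%, inclusive) of its daily values are available; all days of
#' excluded years are set missing (rows are kept so the daily grid stays
#' complete).
#'
#' @param daily Output of [aggregate_daily()].
#' @param min_frac Minimum available fraction of days per year (inclusive).
#' @return Tibble of the same shape; attribute `year_coverage` holds the
#'   per-sensor-year coverage fractions and retention decisions.
#' @export
filter_years <- function(daily, min_frac = 0.4) {
  cov <- daily %>%
    dplyr::group_by(sensor_id, year) %>%
    dplyr::summarise(coverage = mean(!is.na(value)), .groups = "drop") %>%
    dplyr::mutate(retained = .data$coverage >= min_frac)
  out <- daily %>%
    dplyr::left_join(dplyr::select(cov, sensor_id, year, "retained"),
      by = c("sensor_id", "year")
    ) %>%
    dplyr::mutate(value = dplyr::if_else(.data$retained, value, NA_real_)) %>%
    dplyr::select(-"retained")
  attr(out, "year_coverage") <- cov
  out
}

#' Remove annual three-sigma outliers
#'
#' One pass per sensor and calendar year: days whose value lies more than
#' `sd_limit` standard deviations from that year's mean (both computed over
#' the year's available days) are set missing. Years with fewer than two
#' available days, or zero SD, are left untouched.
#'
#' @param daily Year-filtered daily tibble.
#' @param sd_limit SD multiple beyond which a day is an outlier (strict).
#' @return Tibble of the same shape; attribute `outliers_removed` holds the
#'   per-sensor removal counts.
#' @export
remove_outliers <- function(daily, sd_limit = 3) {
  out <- daily %>%
    dplyr::group_by(sensor_id, year) %>%
    dplyr::mutate(value = {
      v <- value
      ok <- !is.na(v)
      if (sum(ok) >= 2) {
        m <- mean(v[ok])
        s <- sd(v[ok])
        if (s > 0) v[ok & abs(v - m) > sd_limit * s] <- NA_real_
      }
      v
    }) %>%
    dplyr::ungroup()
  removed <- daily %>%
    dplyr::mutate(.removed = !is.na(value) & is.na(out$value)) %>%
    dplyr::group_by(sensor_id) %>%
    dplyr::summarise(
      n_removed = sum(.data$.removed),
      n_available = sum(!is.na(value)),
      .groups = "drop"
    )
  attr(out, "outliers_removed") <- removed
  out
}

#' Remove the long-term trend of each sensor series
#'
#' Runs a seasonal-trend decomposition (annual period, loess trend window
#' spanning `trend_years` years, 1095 days by default) per sensor and
#' subtracts the trend component. The decomposition requires a complete
#' series, so missing days are linearly interpolated on a working copy used
#' only for trend estimation; output days that were missing stay missing.
#'
#' @param daily Outlier-filtered daily tibble.
#' @param trend_years Span of the loess trend window in years.
#' @return Tibble `tree_id`, `sensor_id`, `year`, `doy`, `value`,
#'   `stage = "detrended"`.
#' @export
detrend_longterm <- function(daily, trend_years = 3) {
  stopifnot(trend_years >= 1)
  t_window <- trend_years * DAYS_PER_YEAR
  if (t_window %% 2 == 0) t_window <- t_window + 1
  daily %>%
    dplyr::arrange(tree_id, sensor_id, year, doy) %>%
    dplyr::group_by(tree_id, sensor_id) %>%
    dplyr::mutate(value = detrend_one(value, t_window, sensor_id[1])) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(stage = "detrended")
}

detrend_one <- function(x, t_window, id) {
  yrs_retained <- sum(tapply(!is.na(x), (seq_along(x) - 1) %/% DAYS_PER_YEAR, any))
  if (yrs_retained < 3) {
    stop(sprintf(
      "sensor '%s': only %d year(s) with data, need >= 3 for trend removal",
      id, yrs_retained
    ), call. = FALSE)
  }
  xi <- zoo::na.approx(x, na.rm = FALSE, rule = 2)
  dec <- stl(ts(xi, frequency = DAYS_PER_YEAR),
    s.window = "periodic", t.window = t_window
  )
  x - as.numeric(dec$time.series[, "trend"])
}

#' Homogenize interannual variability with a moving-window annual SD
#'
#' For each calendar year the standard deviation is computed over all
#' available values in a `window_years`-year window of neighbouring years
#' (centred by default; truncated at the record edges), and every value of
#' the year is divided by it. This adjusts for variability changes caused by
#' decreasing sensor signal strength.
#'
#' @param detrended Detrended daily tibble.
#' @param window_years Width of the moving window in years (odd for the
#'   centred alignment).
#' @param align `"center"` (year +/- 1 for a 3-year window) or `"trailing"`
#'   (the year and the two before it).
#' @return Tibble with `stage = "normalized"` and dimensionless values.
#' @export
normalize_variability <- function(detrended, window_years = 3,
                                  align = c("center", "trailing")) {
  align <- match.arg(align)
  stopifnot(window_years >= 1)
  detrended %>%
    dplyr::group_by(tree_id, sensor_id) %>%
    dplyr::mutate(value = {
      divisors <- moving_window_sd(value, year, window_years, align, sensor_id[1])
      as.numeric(value / divisors[as.character(year)])
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(stage = "normalized")
}

moving_window_sd <- function(value, year, window_years, align, id,
                             tol = 1e-8) {
  years <- sort(unique(year))
  half <- (window_years - 1) %/% 2
  out <- vapply(years, function(y) {
    win <- if (align == "center") (y - half):(y + half) else (y - window_years + 1):y
    v <- value[year %in% win]
    if (sum(!is.na(v)) < 2) {
      return(NA_real_)
    }
    sd(v, na.rm = TRUE)
  }, numeric(1))
  bad <- !is.na(out) & out < tol
  if (any(bad)) {
    stop(sprintf(
      "sensor '%s': near-constant signal in window around year(s) %s",
      id, paste(years[bad], collapse = ", ")
    ), call. = FALSE)
  }
  names(out) <- as.character(years)
  out
}

#' Average processed sensors per tree
#'
#' Per-day mean over all sensors of a tree that have a value that day; a day
#' is missing only when every sensor is missing. The number of contributing
#' sensors is recorded.
#'
#' @param processed Normalized per-sensor tibble (possibly several trees).
#' @return Tibble `tree_id`, `year`, `doy`, `value`, `n_sensors`,
#'   `stage = "tree_mean"`.
#' @export
combine_sensors <- function(processed) {
  if (nrow(processed) == 0) stop("no sensor series supplied", call. = FALSE)
  processed %>%
    dplyr::group_by(tree_id, year, doy) %>%
    dplyr::summarise(
      n_sensors = sum(!is.na(value)),
      value = if (any(!is.na(value))) mean(value, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) %>%
    dplyr::select(tree_id, year, doy, value, n_sensors) %>%
    dplyr::mutate(stage = "tree_mean") %>%
    dplyr::arrange(tree_id, year, doy)
}

#' Run the full sap-flow processing pipeline
#'
#' Applies, per sensor, daytime aggregation, year-coverage filtering, annual
#' 3-SD outlier removal, seasonal-trend removal and moving-window variance
#' normalization, then averages sensors within each tree. Steps never create
#' values on days that had none.
#'
#' @inheritParams aggregate_daily
#' @param min_day_frac Minimum daytime availability for a daily value.
#' @param min_year_frac Minimum daily coverage for a year to be retained.
#' @param outlier_sd Annual outlier threshold in SDs.
#' @param trend_years Loess trend window span (years).
#' @param window_years Moving-window width for variance normalization.
#' @param window_align Moving-window alignment, `"center"` or `"trailing"`.
#' @param exclude_sensors Optional character vector of `sensor_id`s to drop
#'   before processing (robustness variant for strongly degraded sensors).
#' @return Per-tree tibble as from [combine_sensors()]; attribute `report`
#'   holds per-sensor counts of available days, removed outliers and
#'   retained years.
#' @examples
#' cfg <- scenario_config(start_year = 2003, end_year = 2010,
#'   drought_year = 2007, post_drought_years = 2008:2009, seed = 3)
#' sens <- simulate_sensors(generate_fluxes(generate_drivers(cfg), cfg), cfg)
#' trees <- process_sapflow(sens)
#' attr(trees, "report")
#' @export
process_sapflow <- function(sensors,
                            min_day_frac = 0.7,
                            min_year_frac = 0.4,
                            outlier_sd = 3,
                            trend_years = 3,
                            window_years = 3,
                            window_align = "center",
                            exclude_sensors = NULL) {
  if (!is.null(exclude_sensors)) {
    sensors <- dplyr::filter(sensors, !sensor_id %in% exclude_sensors)
    if (nrow(sensors) == 0) stop("all sensors excluded", call. = FALSE)
  }
  agg <- aggregate_daily(sensors, min_frac = min_day_frac)
  filt <- filter_years(agg, min_frac = min_year_frac)
  clean <- remove_outliers(filt, sd_limit = outlier_sd)
  detr <- detrend_longterm(clean, trend_years = trend_years)
  norm <- normalize_variability(detr,
    window_years = window_years,
    align = window_align
  )
  out <- combine_sensors(norm)

  cov <- attr(filt, "year_coverage")
  rem <- attr(clean, "outliers_removed")
  report <- agg %>%
    dplyr::group_by(tree_id, sensor_id) %>%
    dplyr::summarise(n_days_aggregated = sum(!is.na(value)), .groups = "drop") %>%
    dplyr::left_join(
      cov %>% dplyr::group_by(sensor_id) %>%
        dplyr::summarise(
          n_years_retained = sum(.data$retained),
          n_years_dropped = sum(!.data$retained), .groups = "drop"
        ),
      by = "sensor_id"
    ) %>%
    dplyr::left_join(dplyr::select(rem, sensor_id, "n_removed"), by = "sensor_id") %>%
    dplyr::rename(n_outliers_removed = "n_removed")
  attr(out, "report") <- report
  out
}
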