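# Cross-instrument flux normalization.
#
# Eddy-covariance setups are replaced over long records; level and variance
# shifts between instrument eras are removed by z-scoring each era
# separately and concatenating the standardized segments.

# segment index per row given break years (segment changes at 1 January of
# each break year)
segment_index <- function(year, breaks) {
  findInterval(year, sort(breaks)) + 1L
}

#' Standardize a flux series segment-wise across instrument eras
#'
#' Within each segment (instrument era) the series is z-scored: the segment
#' mean is subtracted and the result divided by the segment's sample SD,
#' both computed over valid days. Segments are delimited by `breaks`, the
#' years at whose 1 January a new instrument era starts (default 2014, the
#' conventional pre/post changeover). Missing values pass through untouched.
#'
#' @param series Tibble with columns `year`, `doy`, `value` (one variable).
#' @param breaks Integer vector of era-start years; empty for a single
#'   segment.
#' @param min_days Minimum valid days required per segment.
#' @return Tibble of the same shape with dimensionless values; attribute
#'   `segments` summarises each segment's span, mean and SD.
#' @examples
#' x <- tibble::tibble(year = 2013, doy = 1:3, value = c(1, 2, 3))
#' normalize_segments(x, breaks = integer())$value
#' @export
normalize_segments <- function(series, breaks = 2014L, min_days = 30L) {
  stopifnot(all(c("year", "doy", "value") %in% names(series)))
  seg <- segment_index(series$year, breaks)
  stats <- lapply(sort(unique(seg)), function(s) {
    v <- series$value[seg == s]
    n_ok <- sum(!is.na(v))
    if (n_ok < min_days) {
      stop(sprintf(
        "segment %d has %d valid day(s), need >= %d", s, n_ok, min_days
      ), call. = FALSE)
    }
    s_sd <- sd(v, na.rm = TRUE)
    if (!is.finite(s_sd) || s_sd == 0) {
      stop(sprintf("segment %d has zero variance", s), call. = FALSE)
    }
    list(segment = s, mean = mean(v, na.rm = TRUE), sd = s_sd, n = n_ok)
  })
  stats_df <- dplyr::bind_rows(stats)
  mu <- stats_df$mean[match(seg, stats_df$segment)]
  sigma <- stats_df$sd[match(seg, stats_df$segment)]
  out <- dplyr::mutate(series, value = (value - mu) / sigma)
  attr(out, "segments") <- stats_df
  out
}

#' Compute water use efficiency as GPP / ET
#'
#' Forms the per-day ratio of gross primary productivity to
#' evapotranspiration on the physical (pre-normalization) scale. Days where
#' either input is missing, or where ET falls below a floor (default the
#' 1st percentile of positive ET, guarding against near-zero-denominator
#' blow-ups), are set missing.
#'
#' @param gpp,et Tibbles with columns `year`, `doy`, `value` on the same
#'   calendar.
#' @param et_floor Minimum ET for the ratio to be defined; `NULL` for the
#'   default percentile rule.
#' @return Tibble `year`, `doy`, `value`; attribute `n_floored` counts days
#'   suppressed by the ET floor.
#' @export
compute_wue <- function(gpp, et, et_floor = NULL) {
  joined <- dplyr::inner_join(
    dplyr::select(gpp, year, doy, gpp = value),
    dplyr::select(et, year, doy, et = value),
    by = c("year", "doy")
  )
  if (is.null(et_floor)) {
    pos <- joined$et[!is.na(joined$et) & joined$et > 0]
    if (length(pos) == 0) stop("no positive ET values", call. = FALSE)
    et_floor <- as.numeric(quantile(pos, 0.01))
  }
  floored <- !is.na(joined$et) & joined$et < et_floor
  out <- joined %>%
    dplyr::mutate(
      value = dplyr::if_else(
        !is.na(.data$gpp) & !is.na(.data$et) & .data$et >= et_floor,
        .data$gpp / .data$et, NA_real_
      )
    ) %>%
    dplyr::select(year, doy, value)
  attr(out, "n_floored") <- sum(floored & !is.na(joined$gpp))
  attr(out, "et_floor") <- et_floor
  out
}

#' Remove a linear long-term trend from a series
#'
#' Fits ordinary least squares of value on time over valid days and returns
#' the residuals plus the overall mean, preserving the series level while
#' removing the trend (used, e.g., to remove a long-term greening trend from
#' a satellite greenness index before drought analysis).
#'
#' @param series Tibble with columns `year`, `doy`, `value`.
#' @return Tibble of the same shape; attributes `slope` (per day),
#'   `slope_se`, `slope_p` report the removed trend and its significance.
#' @export
detrend_linear <- function(series) {
  stopifnot(all(c("year", "doy", "value") %in% names(series)))
  ok <- !is.na(series$value)
  if (!any(ok)) stop("series has no valid values", call. = FALSE)
  t <- day_index(series$year, series$doy, min(series$year))
  fit <- lm(series$value[ok] ~ t[ok])
  # summary.lm warns on an exactly linear input; the slope is still valid
  ct <- suppressWarnings(summary(fit))$coefficients
  out <- series
  out$value <- series$value - (coef(fit)[1] + coef(fit)[2] * t) +
    mean(series$value[ok])
  attr(out, "slope") <- unname(coef(fit)[2])
  attr(out, "slope_se") <- ct[2, 2]
  attr(out, "slope_p") <- ct[2, 4]
  out
}
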