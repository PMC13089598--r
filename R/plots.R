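# Figures. Residual-vs-envelope plot for a fitted legacy analysis, annual
# cycles with record-extreme shading, and the focal-year anomaly dot plot.

#' Plot post-drought residuals against the uncertainty envelope
#'
#' Weekly mean residuals of the predicted years (one coloured line per
#' year) over the leave-one-out percentile envelope (dark ribbon 25th-75th,
#' light ribbon 5th-95th); weeks outside the 5th-95th band are starred.
#'
#' @param object A `legacy_analysis` from [run_legacy_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.legacy_analysis <- function(object, ...) {
  bands <- object$bands
  weekly <- dplyr::mutate(object$weekly, year = factor(year))
  flagged <- dplyr::filter(weekly, !is.na(flag), flag != "none")
  ggplot2::ggplot(bands, ggplot2::aes(x = week)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = p5, ymax = p95), fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = p25, ymax = p75), fill = "grey65") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_line(
      data = weekly,
      ggplot2::aes(y = weekly_residual, colour = year)
    ) +
    ggplot2::geom_point(
      data = flagged,
      ggplot2::aes(y = weekly_residual, colour = year),
      shape = 8, size = 2
    ) +
    ggplot2::labs(
      x = "week of year", y = "model residual (observed - predicted)",
      colour = NULL,
      title = sprintf(
        "Post-drought residuals vs. leave-one-out envelope (OOB R² = %.2f)",
        object$oob_score
      )
    ) +
    ggplot2::theme_minimal()
}

#' Annual cycles with record-extreme shading
#'
#' All years in grey, highlighted years in colour, with shaded day-of-year
#' ranges where the focal year is the pointwise record extreme for more
#' than a week (see [extreme_runs()]). A centred moving average (default 4
#' weeks) is applied for display.
#'
#' @param series Tibble `year`, `doy`, `value`.
#' @param focal_year Drought year to shade extremes for.
#' @param highlight_years Years drawn in colour (default focal year and the
#'   two after).
#' @param smooth_window Display smoothing window in days.
#' @return A ggplot object.
#' @export
plot_annual_cycles <- function(series, focal_year,
                               highlight_years = focal_year + 0:2,
                               smooth_window = 28L) {
  runs <- extreme_runs(series, focal_year)
  sm <- series %>%
    dplyr::group_by(year) %>%
    dplyr::group_modify(~ smooth_series(dplyr::mutate(.x, year = .y$year), smooth_window)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      highlight = ifelse(year %in% highlight_years, as.character(year), "other")
    )
  p <- ggplot2::ggplot(sm, ggplot2::aes(x = doy, y = value, group = year))
  if (nrow(runs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = runs,
      ggplot2::aes(
        xmin = start_doy, xmax = end_doy, ymin = -Inf, ymax = Inf,
        fill = kind
      ),
      alpha = 0.2, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(values = c(min = "tan3", max = "steelblue3"))
  }
  p +
    ggplot2::geom_line(
      data = dplyr::filter(sm, .data$highlight == "other"),
      colour = "grey75", linewidth = 0.3
    ) +
    ggplot2::geom_line(
      data = dplyr::filter(sm, .data$highlight != "other"),
      ggplot2::aes(colour = .data$highlight), linewidth = 0.6
    ) +
    ggplot2::labs(
      x = "day of year", y = "value", colour = "year",
      fill = "record extreme"
    ) +
    ggplot2::theme_minimal()
}

#' Dot-and-box view of a focal year against all years
#'
#' Period means of every year as boxplots with the focal year overlaid,
#' per variable and period (whole year and half-years).
#'
#' @param series Tibble `year`, `doy`, `value`, optionally `variable`.
#' @param focal_year Focal (drought) year.
#' @return A ggplot object.
#' @export
plot_period_impact <- function(series, focal_year) {
  has_var <- "variable" %in% names(series)
  if (!has_var) series$variable <- "value"
  means <- purrr::map_dfr(PERIOD_CHOICES, function(p) {
    series %>%
      dplyr::filter(doy %in% period_doys(p), !is.na(value)) %>%
      dplyr::group_by(variable, year) %>%
      dplyr::summarise(mean_value = mean(value), .groups = "drop") %>%
      dplyr::mutate(period = factor(p, levels = PERIOD_CHOICES))
  })
  ggplot2::ggplot(means, ggplot2::aes(x = period, y = .data$mean_value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.08, size = 1, colour = "grey55") +
    ggplot2::geom_point(
      data = dplyr::filter(means, year == focal_year),
      colour = "firebrick", size = 2.5
    ) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "period mean") +
    ggplot2::theme_minimal()
}
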