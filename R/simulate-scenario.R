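#' Generate a synthetic daily hydro-meteorological driver table
#'
#' Produces one row per day of the configured record. Shortwave radiation,
#' air temperature, vapour pressure deficit and wind speed are each an annual
#' harmonic plus an AR(1) anomaly. Precipitation is an intermittent
#' occurrence-amount process (seasonal wet-day probability, gamma amounts);
#' during the configured drought months of the drought year, amounts are
#' scaled by `1 - deficit`, and throughout the first post-drought year by
#' `1 + surplus`. Soil water content integrates precipitation through a
#' simple bucket balance whose loss term is proportional to a VPD- and
#' temperature-driven demand and to the current store, clipped to `[0, 1]`.
#'
#' @param config A [scenario_config()].
#' @return A tibble with columns `year`, `doy`, `SWC`, `VPD`, `SW_IN`, `TA`,
#'   `WS`, `precip`; no missing values (gaps are a sensor-level phenomenon).
#' @examples
#' drv <- generate_drivers(scenario_config(seed = 1))
#' range(drv$SWC)
#' @export
generate_drivers <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  grid <- seq_days(config$start_year, config$end_year)
  n <- nrow(grid)
  p <- config$driver_params

  harmonic <- function(par) {
    par$mean + par$amp * cos(2 * pi * (grid$doy - par$phase) / DAYS_PER_YEAR)
  }
  ar1 <- function(par) {
    innov <- rnorm(n, 0, par$sd)
    as.numeric(stats::filter(innov, par$ar1, method = "recursive"))
  }
  smooth_driver <- function(par) pmax(harmonic(par) + ar1(par), par$min)

  SW_IN <- smooth_driver(p$SW_IN)
  TA <- smooth_driver(p$TA)
  VPD <- smooth_driver(p$VPD)
  WS <- smooth_driver(p$WS)

  # intermittent precipitation: seasonal occurrence, gamma amounts
  pp <- p$precip
  p_wet <- pmin(pmax(
    pp$occ_base + pp$occ_amp * cos(2 * pi * (grid$doy - pp$occ_phase) / DAYS_PER_YEAR),
    0
  ), 1)
  wet <- rbinom(n, 1L, p_wet)
  amount <- rgamma(n, shape = pp$amount_shape, scale = pp$amount_mean / pp$amount_shape)
  scale_fac <- rep(1, n)
  in_drought <- grid$year == config$drought_year &
    month_of_doy(grid$doy) %in% config$drought_spec$months
  scale_fac[in_drought] <- 1 - config$drought_spec$deficit
  wet_year <- min(config$post_drought_years)
  scale_fac[grid$year == wet_year] <- scale_fac[grid$year == wet_year] *
    (1 + config$wet_year_spec$surplus)
  precip <- wet * amount * scale_fac

  # bucket soil water balance (store as fraction of capacity)
  ps <- p$SWC
  demand <- ps$demand_vpd * VPD + ps$demand_ta * pmax(TA, 0) # mm/day at full store
  swc <- numeric(n)
  s <- ps$init
  for (i in seq_len(n)) {
    s <- s + (precip[i] - demand[i] * s) / ps$capacity_mm
    s <- min(max(s, 0), 1)
    swc[i] <- s
  }

  tibble(
    year = grid$year, doy = grid$doy,
    SWC = swc, VPD = VPD, SW_IN = SW_IN, TA = TA, WS = WS, precip = precip
  )
}

# response factors: saturating light, unimodal temperature, soil-moisture
# limitation below a stress threshold, decreasing VPD response
response_signal <- function(drivers, par) {
  g1 <- drivers$SW_IN / (drivers$SW_IN + par$sw_half)
  g2 <- exp(-((drivers$TA - par$ta_opt) / par$ta_sd)^2)
  g3 <- pmin(1, drivers$SWC / par$swc_thresh)
  g4 <- 1 / (1 + par$vpd_k * drivers$VPD)
  par$A * g1 * g2 * g3 * g4
}

# multiplicative legacy suppression, 1 before onset, recovering with
# e-folding time tau afterwards
legacy_multiplier <- function(year, doy, spec) {
  t_rel <- day_index(year, doy, spec$onset_year) - (spec$onset_doy - 1L)
  ifelse(t_rel >= 0, 1 - spec$lambda * exp(-t_rel / spec$tau), 1)
}

#' Generate latent flux series from drivers
#'
#' GPP, ET and stand sap flow respond multiplicatively to the drivers:
#' `A * g1(SW_IN) * g2(TA) * g3(SWC) * g4(VPD)` with saturating `g1`,
#' unimodal `g2`, `g3` increasing below a soil-moisture stress threshold and
#' `g4` decreasing in VPD; Gaussian observation noise is added and the sum
#' truncated at zero. The whole flux is then multiplied by the legacy
#' multiplier `1 - lambda * exp(-(t - onset)/tau)` for days at or after the
#' configured onset. Noise is drawn independently of `lambda`, so scenarios
#' sharing a seed but differing in `lambda` are identical before onset.
#'
#' @param drivers Driver table from [generate_drivers()].
#' @param config A [scenario_config()].
#' @return A tibble with columns `year`, `doy`, `GPP_true`, `ET_true`,
#'   `sapflow_true`, `legacy_multiplier`, with an attribute `tree_factors`
#'   (named per-tree multiplicative factors applied by [simulate_sensors()]).
#' @examples
#' cfg <- scenario_config(seed = 1)
#' fx <- generate_fluxes(generate_drivers(cfg), cfg)
#' head(fx)
#' @export
generate_fluxes <- function(drivers, config) {
  stopifnot(inherits(config, "scenario_config"))
  req <- c("year", "doy", "SWC", "VPD", "SW_IN", "TA", "WS", "precip")
  missing_cols <- setdiff(req, names(drivers))
  if (length(missing_cols) > 0) {
    stop(
      "drivers are missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  set.seed(config$seed + 1L)
  n <- nrow(drivers)
  rp <- config$response_params

  # fixed draw order, independent of lambda, so null/alternative runs couple
  tree_factors <- exp(rnorm(
    config$sensor_spec$n_trees, 0,
    rp$sapflow$tree_factor_sd
  ))
  names(tree_factors) <- paste0("tree", seq_along(tree_factors))
  noise <- list(
    GPP = rnorm(n, 0, rp$GPP$noise_sd),
    ET = rnorm(n, 0, rp$ET$noise_sd),
    sapflow = rnorm(n, 0, rp$sapflow$noise_sd)
  )

  mult <- legacy_multiplier(drivers$year, drivers$doy, config$legacy_spec)
  flux <- function(nm) {
    pmax(response_signal(drivers, rp[[nm]]) + noise[[nm]], 0) * mult
  }

  out <- tibble(
    year = drivers$year, doy = drivers$doy,
    GPP_true = flux("GPP"),
    ET_true = flux("ET"),
    sapflow_true = flux("sapflow"),
    legacy_multiplier = mult
  )
  attr(out, "tree_factors") <- tree_factors
  out
}

# per-sensor gain: exponential decay since installation, reset at
# replacements (replacement at 1 January of each replacement year)
sensor_gain <- function(year, doy, rate, config) {
  t <- day_index(year, doy, config$start_year)
  resets <- sort(unique(c(
    0,
    day_index(config$sensor_spec$replacement_years, 1L, config$start_year)
  )))
  last_reset <- resets[findInterval(t, resets)]
  exp(-rate * (t - last_reset) / DAYS_PER_YEAR)
}

#' Simulate degrading multi-sensor sap-flow observations
#'
#' Each tree carries `sensors_per_tree` sensors observing the tree-level
#' latent sap flow (stand sap flow times the tree's multiplicative factor).
#' A sensor's value is `gain(t) * truth * (1 + noise)` where the gain decays
#' exponentially from 1 at installation and resets to 1 at each replacement
#' date. Isolated daily gaps, multi-week gap blocks, and rare spikes with
#' magnitude well beyond three annual standard deviations are injected at
#' the configured rates. With `resolution = "halfhourly"` each day is
#' expanded to 48 slots with a half-sine daytime course (daytime mean equal
#' to the daily value) and near-zero night-time flow.
#'
#' @param fluxes Output of [generate_fluxes()] (carries the per-tree
#'   factors).
#' @param config A [scenario_config()].
#' @return A long tibble of sensor observations: `tree_id`, `sensor_id`,
#'   `year`, `doy`, (`slot`, 1..48, half-hourly only), `value`,
#'   `daytime_flag`.
#' @examples
#' cfg <- scenario_config(start_year = 2003, end_year = 2008, drought_year = 2005,
#'   post_drought_years = 2006:2007, seed = 2)
#' sens <- simulate_sensors(generate_fluxes(generate_drivers(cfg), cfg), cfg)
#' dplyr::count(sens, tree_id, sensor_id)
#' @export
simulate_sensors <- function(fluxes, config) {
  stopifnot(inherits(config, "scenario_config"))
  sp <- config$sensor_spec
  tree_factors <- attr(fluxes, "tree_factors")
  if (is.null(tree_factors)) {
    tree_factors <- rep(1, sp$n_trees)
    names(tree_factors) <- paste0("tree", seq_len(sp$n_trees))
  }
  set.seed(config$seed + 2L)
  n <- nrow(fluxes)
  n_years <- config$end_year - config$start_year + 1
  rates <- rep_len(sp$decay_rates, sp$n_trees * sp$sensors_per_tree)

  out <- vector("list", sp$n_trees * sp$sensors_per_tree)
  k <- 0
  for (tr in seq_len(sp$n_trees)) {
    truth <- fluxes$sapflow_true * tree_factors[tr]
    for (s in seq_len(sp$sensors_per_tree)) {
      k <- k + 1
      gain <- sensor_gain(fluxes$year, fluxes$doy, rates[k], config)
      value <- gain * truth * (1 + rnorm(n, 0, sp$noise_sd))

      # rare spikes: jump to annual mean +/- outlier_mult annual SDs
      spike <- runif(n) < sp$outlier_prob
      if (any(spike)) {
        yr_mean <- stats::ave(value, fluxes$year, FUN = mean)
        yr_sd <- stats::ave(value, fluxes$year, FUN = sd)
        sign <- sample(c(-1, 1), sum(spike), replace = TRUE)
        value[spike] <- yr_mean[spike] + sign * sp$outlier_mult * yr_sd[spike]
      }

      # isolated gaps and multi-week blocks
      gap <- runif(n) < sp$gap_prob
      n_blocks <- rpois(1, sp$block_rate * n_years)
      if (n_blocks > 0) {
        starts <- sample.int(n, n_blocks)
        lens <- 7 + rpois(n_blocks, sp$block_len - 7)
        for (b in seq_len(n_blocks)) {
          gap[seq(starts[b], min(n, starts[b] + lens[b] - 1))] <- TRUE
        }
      }
      value[gap] <- NA_real_

      out[[k]] <- tibble(
        tree_id = names(tree_factors)[tr],
        sensor_id = sprintf("%s_s%d", names(tree_factors)[tr], s),
        year = fluxes$year, doy = fluxes$doy,
        value = value
      )
    }
  }
  daily <- dplyr::bind_rows(out)
  if (sp$resolution == "daily") {
    daily$daytime_flag <- TRUE
    return(daily)
  }
  expand_halfhourly(daily, config)
}

# expand a daily sensor table to 48 half-hour slots per day with a half-sine
# daytime course whose daytime mean equals the daily value
expand_halfhourly <- function(daily, config) {
  daylength_slots <- function(doy) {
    hours <- 12 + 4 * cos(2 * pi * (doy - 172) / DAYS_PER_YEAR)
    2L * as.integer(round(hours))
  }
  per_day <- function(value, doy) {
    m <- daylength_slots(doy)
    first <- 24L - m %/% 2L + 1L
    slots <- seq_len(48L)
    day <- slots >= first & slots < first + m
    shape <- numeric(48L)
    shape[day] <- (pi / 2) * sin(pi * (seq_len(m) - 0.5) / m)
    list(value = value * shape, daytime = day)
  }
  # precompute day templates per doy to avoid 48x row-wise work
  tmpl <- lapply(seq_len(DAYS_PER_YEAR), function(d) per_day(1, d))
  n <- nrow(daily)
  idx <- rep(seq_len(n), each = 48L)
  shape <- unlist(lapply(daily$doy, function(d) tmpl[[d]]$value))
  daytime <- unlist(lapply(daily$doy, function(d) tmpl[[d]]$daytime))
  tibble(
    tree_id = daily$tree_id[idx],
    sensor_id = daily$sensor_id[idx],
    year = daily$year[idx],
    doy = daily$doy[idx],
    slot = rep(seq_len(48L), n),
    value = daily$value[idx] * shape,
    daytime_flag = daytime
  )
}
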