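#' Configure a synthetic drought scenario
#'
#' Builds the full parameterization of a synthetic experiment: a multi-year
#' daily record of Mediterranean-type hydro-meteorological drivers, an
#' embedded severe late-season drought year followed by a wet year, nonlinear
#' flux responses, a multi-sensor sap-flow observation layer with progressive
#' gain decay, and an optional injected post-drought suppression (the
#' "legacy effect") for parameter-recovery experiments.
#'
#' The defaults emulate the study design the package targets: a 2003--2021
#' record with a severe 2017 drought whose July--September precipitation is
#' 11% of the climatological mean, a first post-drought year that is the
#' wettest of the record (+56% precipitation), five instrumented trees with
#' two thermal-dissipation sensors each, and two post-drought years.
#'
#' @param start_year,end_year First and last calendar year of the record.
#' @param drought_year Focal drought year.
#' @param post_drought_years Years treated as post-drought (excluded from all
#'   model training); default the two years after `drought_year`.
#' @param driver_params Named list of per-driver parameters; see Details.
#'   Partial lists override the defaults element-wise.
#' @param drought_spec List with `deficit` (fractional precipitation
#'   reduction in `[0, 1]`) and `months` (integer months of `drought_year`
#'   affected).
#' @param wet_year_spec List with `surplus` (fractional precipitation
#'   increase applied to the first post-drought year).
#' @param response_params Named list (`GPP`, `ET`, `sapflow`) of flux
#'   response coefficients; see Details.
#' @param legacy_spec List with `lambda` (suppression fraction in `[0, 1)`;
#'   0 gives the null scenario), `onset_year`/`onset_doy` (default 1 January
#'   of the first post-drought year), and `tau` (e-folding recovery time in
#'   days).
#' @param sensor_spec List describing the sap-flow observation layer:
#'   `n_trees`, `sensors_per_tree`, `decay_rates` (per-sensor exponential
#'   gain-decay rates per year, recycled across sensors), `replacement_years`
#'   (years at whose 1 January every sensor is replaced and its gain reset;
#'   default one mid-record replacement), `gap_prob` (per-day isolated gap
#'   probability), `block_rate` (multi-week gap blocks per sensor-year),
#'   `block_len` (mean block length, days), `outlier_prob` (per-day spike
#'   probability), `outlier_mult` (spike magnitude in annual SDs, > 3),
#'   `noise_sd` (relative measurement noise), `resolution` ("daily" or
#'   "halfhourly").
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the configuration including the seed.
#'
#' @details
#' Each entry of `driver_params` for `SW_IN`, `TA`, `VPD`, `WS` is a list
#' `(mean, amp, phase, ar1, sd, min)`: an annual harmonic
#' `mean + amp * cos(2 * pi * (doy - phase) / 365)` plus an AR(1) anomaly with
#' persistence `ar1` and innovation SD `sd`, floored at `min`. `precip` uses
#' an intermittent occurrence--amount process
#' (`occ_base`, `occ_amp`, `occ_phase`, `amount_mean`, `amount_shape`), and
#' `SWC` a bucket balance (`capacity_mm`, `demand_vpd`, `demand_ta`, `init`)
#' that integrates precipitation history.
#'
#' Each entry of `response_params` is a list
#' `(A, sw_half, ta_opt, ta_sd, swc_thresh, vpd_k, noise_sd)` parameterizing
#' the multiplicative response
#' `A * g1(SW_IN) * g2(TA) * g3(SWC) * g4(VPD)` with saturating `g1`,
#' unimodal `g2`, below-threshold-limiting `g3` and decreasing `g4`
#' (see [generate_fluxes()]). `sapflow` additionally takes `tree_factor_sd`,
#' the SD of the log-normal per-tree multiplicative factors.
#'
#' @return An object of class `scenario_config` (a validated named list).
#' @seealso [generate_drivers()], [generate_fluxes()], [simulate_sensors()]
#' @examples
#' cfg <- scenario_config(seed = 1)
#' cfg$drought_year
#' @export
scenario_config <- function(start_year = 2003,
                            end_year = 2021,
                            drought_year = 2017,
                            post_drought_years = drought_year + 1:2,
                            driver_params = list(),
                            drought_spec = list(),
                            wet_year_spec = list(),
                            response_params = list(),
                            legacy_spec = list(),
                            sensor_spec = list(),
                            seed = 1L) {
  defaults <- list(
    driver_params = list(
      SW_IN = list(mean = 170, amp = 130, phase = 172, ar1 = 0.6, sd = 30, min = 5),
      TA = list(mean = 13.5, amp = 8.5, phase = 200, ar1 = 0.8, sd = 1.6, min = -Inf),
      VPD = list(mean = 7.5, amp = 6, phase = 200, ar1 = 0.7, sd = 1.8, min = 0.1),
      WS = list(mean = 3.2, amp = 0.7, phase = 20, ar1 = 0.5, sd = 0.8, min = 0.1),
      precip = list(
        occ_base = 0.24, occ_amp = 0.07, occ_phase = 20,
        amount_mean = 11, amount_shape = 0.65
      ),
      SWC = list(capacity_mm = 250, demand_vpd = 0.28, demand_ta = 0.09, init = 0.6)
    ),
    drought_spec = list(deficit = 0.89, months = 7:9),
    wet_year_spec = list(surplus = 0.56),
    response_params = list(
      GPP = list(
        A = 8, sw_half = 120, ta_opt = 18, ta_sd = 10,
        swc_thresh = 0.35, vpd_k = 0.04, noise_sd = 0.5
      ),
      ET = list(
        A = 4, sw_half = 150, ta_opt = 22, ta_sd = 12,
        swc_thresh = 0.30, vpd_k = 0.015, noise_sd = 0.25
      ),
      sapflow = list(
        A = 3, sw_half = 140, ta_opt = 21, ta_sd = 12,
        swc_thresh = 0.30, vpd_k = 0.02, noise_sd = 0.2,
        tree_factor_sd = 0.08
      )
    ),
    legacy_spec = list(
      lambda = 0,
      onset_year = min(post_drought_years),
      onset_doy = 1L,
      tau = 180
    ),
    sensor_spec = list(
      n_trees = 5L,
      sensors_per_tree = 2L,
      decay_rates = c(0.1, 0.2),
      replacement_years = floor((start_year + end_year) / 2),
      gap_prob = 0.01,
      block_rate = 0.08,
      block_len = 21,
      outlier_prob = 0.002,
      outlier_mult = 5,
      noise_sd = 0.05,
      resolution = "daily"
    )
  )

  cfg <- structure(
    list(
      start_year = as.integer(start_year),
      end_year = as.integer(end_year),
      drought_year = as.integer(drought_year),
      post_drought_years = as.integer(post_drought_years),
      driver_params = modify_defaults(defaults$driver_params, driver_params),
      drought_spec = utils::modifyList(defaults$drought_spec, drought_spec),
      wet_year_spec = utils::modifyList(defaults$wet_year_spec, wet_year_spec),
      response_params = modify_defaults(defaults$response_params, response_params),
      legacy_spec = utils::modifyList(defaults$legacy_spec, legacy_spec),
      sensor_spec = utils::modifyList(defaults$sensor_spec, sensor_spec),
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
  validate_scenario_config(cfg)
}

# element-wise merge of nested parameter lists
modify_defaults <- function(defaults, user) {
  if (length(user) == 0) {
    return(defaults)
  }
  stopifnot(is.list(user), !is.null(names(user)))
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0) {
    stop("unknown parameter group(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], user[[nm]])
  }
  defaults
}

validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (end_year < start_year) {
      stop("end_year must be >= start_year", call. = FALSE)
    }
    if (drought_year < start_year || drought_year > end_year) {
      stop("drought_year outside the record", call. = FALSE)
    }
    if (length(post_drought_years) < 1 ||
      any(post_drought_years <= drought_year) ||
      any(post_drought_years > end_year)) {
      stop("post_drought_years must lie strictly after drought_year and within the record",
        call. = FALSE
      )
    }
    if (drought_spec$deficit < 0 || drought_spec$deficit > 1) {
      stop("drought deficit fraction must be in [0, 1]", call. = FALSE)
    }
    if (wet_year_spec$surplus < 0) {
      stop("wet-year surplus fraction must be >= 0", call. = FALSE)
    }
    if (legacy_spec$lambda < 0 || legacy_spec$lambda >= 1) {
      stop("legacy suppression lambda must be in [0, 1)", call. = FALSE)
    }
    if (legacy_spec$tau <= 0) stop("legacy tau must be positive", call. = FALSE)
    if (sensor_spec$n_trees < 1 || sensor_spec$sensors_per_tree < 1) {
      stop("sensor_spec must define at least one sensor per tree", call. = FALSE)
    }
    if (any(sensor_spec$replacement_years < start_year |
      sensor_spec$replacement_years > end_year)) {
      stop("sensor replacement dates outside the record", call. = FALSE)
    }
    if (!sensor_spec$resolution %in% c("daily", "halfhourly")) {
      stop("sensor resolution must be 'daily' or 'halfhourly'", call. = FALSE)
    }
  })
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf(
    "  record: %d-%d, drought year %d, post-drought %s\n",
    x$start_year, x$end_year, x$drought_year,
    paste(x$post_drought_years, collapse = ", ")
  ))
  cat(sprintf(
    "  drought: %.0f%% precip deficit in months %s; wet year surplus +%.0f%%\n",
    100 * x$drought_spec$deficit,
    paste(range(x$drought_spec$months), collapse = "-"),
    100 * x$wet_year_spec$surplus
  ))
  cat(sprintf(
    "  legacy: lambda = %.2f, tau = %.0f d, onset %d-%03d\n",
    x$legacy_spec$lambda, x$legacy_spec$tau,
    x$legacy_spec$onset_year, x$legacy_spec$onset_doy
  ))
  cat(sprintf(
    "  sensors: %d trees x %d, resolution %s; seed %d\n",
    x$sensor_spec$n_trees, x$sensor_spec$sensors_per_tree,
    x$sensor_spec$resolution, x$seed
  ))
  invisible(x)
}

#' Read or write a scenario configuration as YAML
#'
#' @param path File path.
#' @return `read_scenario_config()` returns a `scenario_config`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(scenario_config, raw)
}

#' @rdname read_scenario_config
#' @param config A `scenario_config` object.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
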