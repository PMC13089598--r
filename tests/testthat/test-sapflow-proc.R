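# hand-built half-hourly day: m daytime slots, k of them observed
halfhourly_day <- function(n_daytime, n_obs, value = 10) {
  stopifnot(n_obs <= n_daytime)
  n_slots <- max(48, n_daytime + 10)
  vals <- rep(NA_real_, n_slots)
  day_slots <- seq_len(n_daytime) + 5
  vals[day_slots[seq_len(n_obs)]] <- value + seq_len(n_obs)
  tibble::tibble(
    tree_id = "t1", sensor_id = "s1", year = 2003, doy = 1,
    slot = seq_len(n_slots), value = vals, daytime_flag = seq_len(n_slots) %in% day_slots
  )
}

test_that("daily aggregation takes the daytime mean above the availability threshold", {
  full <- halfhourly_day(20, 20)
  agg <- aggregate_daily(full)
  expect_equal(agg$value, mean(full$value[full$daytime_flag], na.rm = TRUE))
  expect_equal(agg$stage, "aggregated")

  # 69% availability (inclusive 70% rule): missing
  below <- aggregate_daily(halfhourly_day(100, 69))
  expect_true(is.na(below$value))

  at <- aggregate_daily(halfhourly_day(100, 70))
  expect_false(is.na(at$value))

  # a day with no daytime slots is missing, not an error
  night <- halfhourly_day(20, 20)
  night$daytime_flag <- FALSE
  expect_true(is.na(aggregate_daily(night)$value))

  # daily input passes through
  d <- daily_sensor_table(rnorm(365), 2003)
  expect_equal(aggregate_daily(d)$value, d$value)
})

test_that("years below 40% daily coverage are removed entirely", {
  set.seed(11)
  vals <- rnorm(3 * 365, 10)
  # year 2004: keep only 39% of days; year 2005: exactly 40%
  miss04 <- sample(365, 365 - floor(0.39 * 365))
  miss05 <- sample(365, 365 - 146) # 146/365 = 0.4
  vals[365 + miss04] <- NA
  vals[730 + miss05] <- NA
  d <- daily_sensor_table(vals, 2003:2005)
  out <- filter_years(d)
  expect_true(all(is.na(out$value[out$year == 2004])))
  expect_false(all(is.na(out$value[out$year == 2005])))
  expect_equal(out$value[out$year == 2003], vals[1:365])
})

test_that("retained years match a brute-force coverage count on random gap patterns", {
  set.seed(12)
  for (case in 1:25) {
    n_years <- sample(3:6, 1)
    vals <- rnorm(n_years * 365)
    vals[sample(length(vals), rbinom(1, length(vals), runif(1, 0.3, 0.8)))] <- NA
    d <- daily_sensor_table(vals, 2002 + seq_len(n_years))
    out <- filter_years(d, min_frac = 0.4)
    cov <- oracle_year_coverage(d)
    for (y in names(cov)) {
      year_vals <- out$value[out$year == as.integer(y)]
      if (cov[[y]] >= 0.4) {
        expect_equal(year_vals, d$value[d$year == as.integer(y)])
      } else {
        expect_true(all(is.na(year_vals)))
      }
    }
  }
})

test_that("annual three-sigma outliers are removed in a single pass", {
  # constant year: SD 0, nothing removed
  d <- daily_sensor_table(rep(5, 365), 2003)
  expect_equal(remove_outliers(d)$value, d$value)

  # injected spike at mean + 4 SD of the contaminated year
  set.seed(13)
  vals <- rnorm(365, 10, 1)
  m <- mean(vals[-100])
  s <- sd(vals[-100])
  vals[100] <- m + 4 * s
  d <- daily_sensor_table(vals, 2003)
  out <- remove_outliers(d)
  expect_true(is.na(out$value[100]))
  expect_identical(is.na(out$value), oracle_outliers(d))
  expect_equal(attr(out, "outliers_removed")$n_removed, sum(oracle_outliers(d)))

  # a year with fewer than 2 available days is left untouched
  sparse <- daily_sensor_table(c(100, rep(NA, 364)), 2003)
  expect_equal(remove_outliers(sparse)$value[1], 100)
})

test_that("outlier removal equals the brute-force annual scan on random instances", {
  set.seed(14)
  for (case in 1:25) {
    n_years <- sample(2:4, 1)
    vals <- rnorm(n_years * 365, 10, 2)
    spikes <- sample(length(vals), 10)
    vals[spikes] <- vals[spikes] + sample(c(-1, 1), 10, TRUE) * runif(10, 5, 12)
    vals[sample(length(vals), 200)] <- NA
    d <- daily_sensor_table(vals, 2002 + seq_len(n_years))
    out <- remove_outliers(d)
    expect_identical(is.na(out$value), is.na(d$value) | oracle_outliers(d))
  }
})

test_that("trend removal recovers constants, seasonal cycles and ramps", {
  years <- 2003:2012
  n <- length(years) * 365
  grid_doy <- rep(1:365, length(years))

  const <- detrend_longterm(daily_sensor_table(rep(3, n), years))
  expect_lt(max(abs(const$value)), 1e-6)

  season <- 5 + 2 * sin(2 * pi * grid_doy / 365)
  out <- detrend_longterm(daily_sensor_table(season, years))
  expect_lt(max(abs(out$value - (season - mean(season)))), 0.02 * 2)

  ramp <- seq(0, 4, length.out = n)
  d <- daily_sensor_table(season + ramp, years)
  out <- detrend_longterm(d)
  trend <- d$value - out$value
  expect_gt(cor(trend, ramp), 0.99)
  slope <- coef(lm(out$value ~ seq_len(n)))[2]
  expect_lt(abs(slope) * n, 0.15 * 4) # ramp slope attenuated by > 85%
})

test_that("trend removal refuses records with fewer than three years of data", {
  d <- daily_sensor_table(rnorm(2 * 365), 2003:2004)
  expect_error(detrend_longterm(d), "need >= 3")
  # three grid years but one is all-missing
  vals <- c(rnorm(2 * 365), rep(NA_real_, 365))
  expect_error(detrend_longterm(daily_sensor_table(vals, 2003:2005)), "need >= 3")
})

test_that("variance normalization divides by the pooled moving-window SD", {
  # identical yearly pattern: every windowed SD equals the pattern SD
  pattern <- sin(2 * pi * (1:365) / 365) * 2 / sd(sin(2 * pi * (1:365) / 365))
  d <- daily_sensor_table(rep(pattern, 3), 2003:2005)
  out <- normalize_variability(d)
  expect_equal(out$value, d$value / 2, tolerance = 0.01)
  expect_true(all(out$stage == "normalized"))

  # pooled-SD oracle on three heterogeneous years
  set.seed(15)
  vals <- c(rnorm(365, 0, 1), rnorm(365, 0, 3), rnorm(365, 0, 9))
  d <- daily_sensor_table(vals, 2003:2005)
  out <- normalize_variability(d)
  div1 <- sd(vals[1:730])
  div2 <- sd(vals)
  div3 <- sd(vals[366:1095])
  expect_equal(out$value[1:365], vals[1:365] / div1)
  expect_equal(out$value[366:730], vals[366:730] / div2)
  expect_equal(out$value[731:1095], vals[731:1095] / div3)

  # trailing alignment: year 3 divisor pools years 1-3
  tr <- normalize_variability(d, align = "trailing")
  expect_equal(tr$value[731:1095], vals[731:1095] / sd(vals))

  expect_error(
    normalize_variability(daily_sensor_table(rep(1e-12 * pattern, 3), 2003:2005)),
    "near-constant"
  )
})

test_that("geometric gain decay is homogenized by the moving-window division", {
  set.seed(16)
  years <- 2003:2010
  gains <- rep(2^-(seq_along(years) - 1), each = 365)
  vals <- gains * rnorm(length(gains), 0, 1)
  d <- daily_sensor_table(vals, years)
  out <- normalize_variability(d)
  sd_in <- tapply(d$value, d$year, sd)
  sd_out <- tapply(out$value, out$year, sd)
  expect_lt(max(sd_out) / min(sd_out), max(sd_in) / min(sd_in))
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(sd_out), cv(sd_in))
})

test_that("per-tree averaging uses available sensors only", {
  a <- daily_sensor_table(rnorm(365), 2003, sensor_id = "a")
  b <- daily_sensor_table(rnorm(365), 2003, sensor_id = "b")
  # identical sensors: mean equals either input
  same <- combine_sensors(dplyr::bind_rows(a, a %>% dplyr::mutate(sensor_id = "a2")))
  expect_equal(same$value, a$value)
  expect_true(all(same$n_sensors == 2))

  b$value[1] <- NA
  comb <- combine_sensors(dplyr::bind_rows(a, b))
  expect_equal(comb$value[1], a$value[1])
  expect_equal(comb$n_sensors[1], 1)

  # staggered gaps vs row-wise mean oracle
  set.seed(17)
  a$value[sample(365, 80)] <- NA
  b$value[sample(365, 80)] <- NA
  comb <- combine_sensors(dplyr::bind_rows(a, b))
  oracle <- rowMeans(cbind(a$value, b$value), na.rm = TRUE)
  oracle[is.nan(oracle)] <- NA
  expect_equal(comb$value, oracle)
  expect_error(combine_sensors(a[0, ]), "no sensor")
})

test_that("the full pipeline corrects sensor degradation", {
  cfg <- scenario_config(
    seed = 20,
    sensor_spec = clean_sensor_spec(c(0, 0.3))
  )
  drv <- generate_drivers(cfg)
  fx <- generate_fluxes(drv, cfg)
  sens <- simulate_sensors(fx, cfg)

  norm <- sens %>%
    aggregate_daily() %>%
    filter_years() %>%
    remove_outliers() %>%
    detrend_longterm() %>%
    normalize_variability()

  wide <- tidyr::pivot_wider(
    dplyr::select(norm, sensor_id, year, doy, value),
    names_from = sensor_id, values_from = value
  )
  late <- wide[wide$year >= max(wide$year) - 1, ]
  expect_gt(cor(late$tree1_s1, late$tree1_s2, use = "complete.obs"), 0.9)

  # the processed intact sensor tracks the identically processed truth
  truth <- daily_sensor_table(fx$sapflow_true, cfg$start_year:cfg$end_year) %>%
    detrend_longterm() %>%
    normalize_variability()
  expect_gt(cor(norm$value[norm$sensor_id == "tree1_s1"], truth$value), 0.99)
})

test_that("processing keeps the outlier removal rate below one percent under default noise", {
  cfg <- scenario_config(seed = 21)
  drv <- generate_drivers(cfg)
  fx <- generate_fluxes(drv, cfg)
  trees <- process_sapflow(simulate_sensors(fx, cfg))
  rep <- attr(trees, "report")
  expect_lt(sum(rep$n_outliers_removed) / sum(rep$n_days_aggregated), 0.01)
  expect_equal(nrow(rep), 10)
  expect_setequal(unique(trees$tree_id), paste0("tree", 1:5))
})

test_that("no step creates values on days that had none (no gap-filling)", {
  cfg <- small_scenario(seed = 22)
  drv <- generate_drivers(cfg)
  fx <- generate_fluxes(drv, cfg)
  sens <- simulate_sensors(fx, cfg)
  agg <- aggregate_daily(sens)
  filt <- filter_years(agg)
  cl <- remove_outliers(filt)
  det <- detrend_longterm(cl)
  nor <- normalize_variability(det)
  na_frac <- vapply(
    list(agg, filt, cl, det, nor),
    function(x) mean(is.na(x$value)), numeric(1)
  )
  expect_true(all(diff(na_frac[1:3]) >= 0)) # filtering only removes
  expect_identical(is.na(det$value), is.na(cl$value)) # detrending preserves gaps
  expect_identical(is.na(nor$value), is.na(det$value))
  comb <- combine_sensors(nor)
  per_day_any <- nor %>%
    dplyr::group_by(tree_id, year, doy) %>%
    dplyr::summarise(any_value = any(!is.na(value)), .groups = "drop")
  expect_identical(!is.na(comb$value), per_day_any$any_value)

  # pipeline is a pure function of its input
  expect_identical(process_sapflow(sens), process_sapflow(sens))
})
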