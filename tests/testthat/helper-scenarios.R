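# shared fixtures: small scenarios and brute-force oracles

# compact 8-year scenario for fast end-to-end runs
small_scenario <- function(seed = 1, ...) {
  scenario_config(
    start_year = 2003, end_year = 2010,
    drought_year = 2007, post_drought_years = 2008:2009,
    seed = seed, ...
  )
}

# noise-free sensor layer: one tree, chosen decay rates, no gaps/spikes
clean_sensor_spec <- function(decay_rates, n_trees = 1, sensors_per_tree = length(decay_rates)) {
  list(
    n_trees = n_trees, sensors_per_tree = sensors_per_tree,
    decay_rates = decay_rates,
    gap_prob = 0, block_rate = 0, outlier_prob = 0, noise_sd = 0
  )
}

# hand-built daily sensor table on the full grid of given years
daily_sensor_table <- function(values, years, sensor_id = "s1", tree_id = "t1") {
  grid <- tidyr::expand_grid(year = years, doy = 1:365)
  stopifnot(length(values) == nrow(grid))
  tibble::tibble(
    tree_id = tree_id, sensor_id = sensor_id,
    year = grid$year, doy = grid$doy, value = values
  )
}

# oracle: per-year coverage by direct count
oracle_year_coverage <- function(df) {
  sapply(split(df$value, df$year), function(v) sum(!is.na(v)) / length(v))
}

# oracle: annual 3-SD outlier scan by direct recomputation
oracle_outliers <- function(df, sd_limit = 3) {
  flagged <- rep(FALSE, nrow(df))
  for (y in unique(df$year)) {
    idx <- which(df$year == y & !is.na(df$value))
    if (length(idx) < 2) next
    m <- mean(df$value[idx])
    s <- sd(df$value[idx])
    if (s > 0) flagged[idx] <- abs(df$value[idx] - m) > sd_limit * s
  }
  flagged
}

# oracle: day-by-day strict pointwise extreme scan
oracle_extreme_days <- function(mat, focal_col) {
  # mat: doy x years matrix
  others <- mat[, -focal_col, drop = FALSE]
  ok <- !is.na(mat[, focal_col]) & rowSums(is.na(others)) == 0
  list(
    is_min = ok & mat[, focal_col] < apply(others, 1, min),
    is_max = ok & mat[, focal_col] > apply(others, 1, max)
  )
}

# collapse a logical day vector into runs of at least min_len
oracle_runs <- function(flag, min_len = 8) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}
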