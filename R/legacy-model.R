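# Random-forest residual framework for legacy-effect detection.
#
# A forest learns target = f(hydro-meteorological drivers) on all years
# except the post-drought period, predicts the post-drought period from its
# drivers, and the residuals (observed - predicted) are tested against a
# null envelope built by leave-one-year-out prediction of the non-post-
# drought years. Weeks whose mean residual falls outside the 5th-95th
# percentile band of the held-out residuals are flagged as candidate legacy
# effects.

DEFAULT_PREDICTORS <- c("SWC", "VPD", "SW_IN", "TA", "WS", "precip")

#' Configure the legacy-detection model
#'
#' @param predictors Driver columns used as predictors.
#' @param post_drought_years Years never included in any training set.
#' @param n_trees Number of trees in the forest.
#' @param mtry Predictors tried per split; default the regression convention
#'   `ceiling(p / 3)`.
#' @param engine `"randomForest"` (the conventional implementation, default)
#'   or `"ranger"` (identical algorithm, faster single-threaded; used for
#'   large simulation experiments).
#' @param add_month Append the month of year (integer 1-12) as a predictor
#'   (phenology proxy; robustness variant).
#' @param train_start,train_end Optional calendar-year bounds restricting
#'   the training period (robustness variant), applied on top of the
#'   post-drought exclusion.
#' @param band_stat Aggregate residuals to `"weekly"` means before computing
#'   percentile bands (default, matching weekly flagging) or use `"daily"`
#'   residuals.
#' @param band_scope `"per_week"` percentile bands per week of year
#'   (default) or `"global"` one band for the whole year.
#' @param seed Integer seed controlling the forest's randomness.
#' @return A `legacy_config` object.
#' @export
legacy_config <- function(predictors = DEFAULT_PREDICTORS,
                          post_drought_years,
                          n_trees = 500,
                          mtry = NULL,
                          engine = c("randomForest", "ranger"),
                          add_month = FALSE,
                          train_start = NULL,
                          train_end = NULL,
                          band_stat = c("weekly", "daily"),
                          band_scope = c("per_week", "global"),
                          seed = 1L) {
  stopifnot(length(predictors) > 0, length(post_drought_years) > 0)
  structure(
    list(
      predictors = predictors,
      post_drought_years = as.integer(post_drought_years),
      n_trees = as.integer(n_trees),
      mtry = if (!is.null(mtry)) as.integer(mtry),
      engine = match.arg(engine),
      add_month = isTRUE(add_month),
      train_start = train_start,
      train_end = train_end,
      band_stat = match.arg(band_stat),
      band_scope = match.arg(band_scope),
      seed = as.integer(seed)
    ),
    class = "legacy_config"
  )
}

#' Assemble the training matrix
#'
#' Joins drivers and target by calendar day, keeps rows with a complete
#' predictor set and an observed target, and removes every post-drought year
#' (and, optionally, years outside `train_start`/`train_end` or in
#' `extra_exclude`). A `tree_id` column on the target (pooled sap-flow
#' model) yields one row per tree-day with `tree_id` as a categorical
#' predictor; `add_month` appends the month of year.
#'
#' @param drivers Driver tibble (`year`, `doy`, predictor columns).
#' @param target Tibble `year`, `doy`, `value`, optionally `tree_id`.
#' @param config A [legacy_config()].
#' @param extra_exclude Additional years to exclude from training (e.g. the
#'   drought year itself when hindcasting it).
#' @return Training tibble: `year`, `doy`, predictors, (`month`,
#'   `tree_id`,) `value`.
#' @export
assemble_training <- function(drivers, target, config, extra_exclude = integer()) {
  df <- join_predictors(drivers, target, config)
  df <- dplyr::filter(
    df,
    !year %in% config$post_drought_years,
    !year %in% extra_exclude,
    !is.na(value)
  )
  if (!is.null(config$train_start)) df <- dplyr::filter(df, year >= config$train_start)
  if (!is.null(config$train_end)) df <- dplyr::filter(df, year <= config$train_end)
  if (nrow(df) == 0) stop("empty training set", call. = FALSE)
  df
}

join_predictors <- function(drivers, target, config) {
  missing_cols <- setdiff(config$predictors, names(drivers))
  if (length(missing_cols) > 0) {
    stop(
      "drivers are missing predictor(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  keep <- c("year", "doy", "value", if ("tree_id" %in% names(target)) "tree_id")
  df <- dplyr::inner_join(
    dplyr::select(target, dplyr::all_of(keep)),
    dplyr::select(drivers, year, doy, dplyr::all_of(config$predictors)),
    by = c("year", "doy")
  )
  if (config$add_month) df$month <- month_of_doy(df$doy)
  if ("tree_id" %in% names(df)) df$tree_id <- factor(df$tree_id)
  df <- df[complete.cases(df[, setdiff(names(df), "value")]), ]
  df
}

model_features <- function(df, config) {
  c(
    config$predictors,
    if (config$add_month) "month",
    if ("tree_id" %in% names(df)) "tree_id"
  )
}

# single forest fit; asserts the no-leak invariant on every call
fit_forest <- function(train, config) {
  if (any(train$year %in% config$post_drought_years)) {
    stop("internal error: post-drought year in training mask", call. = FALSE)
  }
  y <- train$value
  if (length(unique(y)) < 2) {
    stop("degenerate target: fewer than two distinct values", call. = FALSE)
  }
  feats <- model_features(train, config)
  x <- as.data.frame(train[, feats])
  mtry <- if (!is.null(config$mtry)) config$mtry else max(1L, ceiling(length(feats) / 3))
  if (config$engine == "randomForest") {
    set.seed(config$seed)
    fit <- randomForest::randomForest(
      x = x, y = y,
      ntree = config$n_trees, mtry = mtry
    )
    oob <- fit$rsq[config$n_trees]
  } else {
    d <- cbind(x, .target = y)
    fit <- ranger::ranger(
      dependent.variable.name = ".target", data = d,
      num.trees = config$n_trees, mtry = mtry,
      seed = config$seed, num.threads = 1,
      respect.unordered.factors = "partition"
    )
    oob <- fit$r.squared
  }
  list(fit = fit, oob = oob, features = feats)
}

predict_forest <- function(model, newdata, config) {
  x <- as.data.frame(newdata[, model$features])
  if (config$engine == "randomForest") {
    as.numeric(predict(model$fit, x))
  } else {
    as.numeric(predict(model$fit, x, num.threads = 1)$predictions)
  }
}

#' Fit the forest and predict a set of days
#'
#' @param training Training tibble from [assemble_training()].
#' @param newdata Prediction rows with complete predictors (same columns).
#' @param config A [legacy_config()].
#' @return List with `predictions` (tibble `year`, `doy`, (`tree_id`,)
#'   `predicted`), `oob_score` (out-of-bag pseudo R-squared) and `model`.
#' @export
fit_predict <- function(training, newdata, config) {
  model <- fit_forest(training, config)
  keep <- c("year", "doy", if ("tree_id" %in% names(newdata)) "tree_id")
  preds <- dplyr::bind_cols(
    newdata[, keep],
    tibble(predicted = predict_forest(model, newdata, config))
  )
  list(predictions = preds, oob_score = model$oob, model = model)
}

# weekly mean residuals; for pooled (tree_id) targets, per-tree residuals
# are first averaged per day
weekly_residuals <- function(daily) {
  if ("tree_id" %in% names(daily)) {
    daily <- daily %>%
      dplyr::group_by(year, doy) %>%
      dplyr::summarise(residual = mean(residual, na.rm = TRUE), .groups = "drop")
  }
  daily %>%
    dplyr::filter(!is.na(residual)) %>%
    dplyr::mutate(week = week_of_year(doy)) %>%
    dplyr::group_by(year, week) %>%
    dplyr::summarise(
      weekly_residual = mean(residual),
      n_days = dplyr::n(), .groups = "drop"
    )
}

#' Leave-one-year-out uncertainty envelope
#'
#' For each non-post-drought year, the forest is retrained with that year
#' (and the post-drought years, and any `extra_exclude` years) withheld and
#' the held-out year is predicted from its drivers. The resulting residuals
#' quantify prediction uncertainty under no-legacy conditions; they are
#' aggregated to weekly means and summarised as 5th/25th/75th/95th
#' percentile bands (per week of year by default). The mean over held-out
#' years of the daily-residual RMSE is reported as `loo_rmse`.
#'
#' @inheritParams assemble_training
#' @return List with `bands` (tibble `week`, `p5`, `p25`, `p75`, `p95`,
#'   `n_years`), `loo_rmse`, `residuals` (held-out daily residuals) and
#'   `n_fits`.
#' @export
loo_uncertainty <- function(drivers, target, config, extra_exclude = integer()) {
  df <- join_predictors(drivers, target, config)
  pool <- dplyr::filter(
    df, !year %in% config$post_drought_years,
    !year %in% extra_exclude, !is.na(value)
  )
  years <- sort(unique(pool$year))
  if (length(years) < 5) {
    stop("need >= 5 non-post-drought years for leave-one-out uncertainty",
      call. = FALSE
    )
  }
  res_list <- vector("list", length(years))
  rmse <- numeric(0)
  for (i in seq_along(years)) {
    y <- years[i]
    train <- assemble_training(drivers, target, config,
      extra_exclude = c(extra_exclude, y)
    )
    heldout <- dplyr::filter(df, year == y, !is.na(value))
    if (nrow(heldout) == 0) {
      warning("held-out year ", y, " has no valid days; skipped")
      next
    }
    model <- fit_forest(train, config)
    heldout$predicted <- predict_forest(model, heldout, config)
    heldout$residual <- heldout$value - heldout$predicted
    res_list[[i]] <- heldout
    rmse <- c(rmse, sqrt(mean(heldout$residual^2)))
  }
  res <- dplyr::bind_rows(res_list)
  bands <- residual_bands(res, config)
  list(
    bands = bands, loo_rmse = mean(rmse),
    residuals = res, n_fits = sum(!vapply(res_list, is.null, logical(1)))
  )
}

residual_bands <- function(res, config) {
  if (config$band_stat == "weekly") {
    r <- weekly_residuals(res)
    r <- dplyr::rename(r, resid = "weekly_residual")
  } else {
    if ("tree_id" %in% names(res)) {
      res <- res %>%
        dplyr::group_by(year, doy) %>%
        dplyr::summarise(residual = mean(residual), .groups = "drop")
    }
    r <- res %>%
      dplyr::mutate(week = week_of_year(doy)) %>%
      dplyr::select(year, week, resid = "residual")
  }
  if (config$band_scope == "global") {
    q <- quantile(r$resid, c(0.05, 0.25, 0.75, 0.95), na.rm = TRUE)
    return(tibble(
      week = 1:52, p5 = q[1], p25 = q[2], p75 = q[3], p95 = q[4],
      n_years = length(unique(r$year))
    ))
  }
  r %>%
    dplyr::group_by(week) %>%
    dplyr::summarise(
      p5 = quantile(resid, 0.05),
      p25 = quantile(resid, 0.25),
      p75 = quantile(resid, 0.75),
      p95 = quantile(resid, 0.95),
      n_years = dplyr::n_distinct(year),
      .groups = "drop"
    )
}

#' Flag weeks whose residual leaves the uncertainty band
#'
#' Weekly mean residuals are compared with the leave-one-out percentile
#' envelope: strictly above the 95th percentile flags `"positive"`, strictly
#' below the 5th `"negative"`, otherwise `"none"`. Values exactly on a band
#' edge are not flagged.
#'
#' @param daily Tibble of daily residuals (`year`, `doy`, `residual`,
#'   optionally `tree_id`).
#' @param bands Band tibble from [loo_uncertainty()].
#' @return Weekly tibble `year`, `week`, `weekly_residual`, `n_days`, bands
#'   and `flag`.
#' @export
flag_legacy <- function(daily, bands) {
  weekly_residuals(daily) %>%
    dplyr::left_join(bands, by = "week") %>%
    dplyr::mutate(flag = dplyr::case_when(
      is.na(weekly_residual) ~ NA_character_,
      weekly_residual > p95 ~ "positive",
      weekly_residual < p5 ~ "negative",
      TRUE ~ "none"
    ))
}

#' Run the full legacy-effect analysis for one target
#'
#' Orchestrates training-set assembly (post-drought years excluded), the
#' full forest fit with out-of-bag skill, prediction of the post-drought
#' days from their hydro-meteorological drivers, the leave-one-year-out
#' uncertainty envelope, and weekly flagging of residuals outside the
#' 5th-95th percentile band.
#'
#' Setting `predict_years` to other years (e.g. the drought year itself)
#' hindcasts those years instead, excluding them from all training and from
#' the uncertainty pool.
#'
#' @inheritParams assemble_training
#' @param predict_years Years to predict and test; default the configured
#'   post-drought years.
#' @return A `legacy_analysis` object: list with `daily` (observed,
#'   predicted, residual), `weekly` (flags), `bands`, `oob_score`,
#'   `loo_rmse`, `trained_years`, `predict_years`, `config`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' \donttest{
#' cfg <- scenario_config(seed = 1)
#' drv <- generate_drivers(cfg)
#' fx <- generate_fluxes(drv, cfg)
#' gpp <- dplyr::transmute(fx, year, doy, value = GPP_true)
#' mc <- legacy_config(post_drought_years = cfg$post_drought_years,
#'   n_trees = 100, engine = "ranger", seed = 1)
#' res <- run_legacy_analysis(drv, gpp, mc)
#' glance(res)
#' }
#' @export
run_legacy_analysis <- function(drivers, target, config, predict_years = NULL) {
  stopifnot(inherits(config, "legacy_config"))
  if (is.null(predict_years)) predict_years <- config$post_drought_years
  extra <- setdiff(predict_years, config$post_drought_years)

  train <- assemble_training(drivers, target, config, extra_exclude = extra)
  df <- join_predictors(drivers, target, config)
  pred_days <- dplyr::filter(df, year %in% predict_years)
  if (nrow(pred_days) == 0) stop("no predictable days in predict_years", call. = FALSE)

  fp <- fit_predict(train, pred_days, config)
  daily <- pred_days %>%
    dplyr::mutate(
      observed = value,
      predicted = fp$predictions$predicted,
      residual = observed - predicted
    ) %>%
    dplyr::select(dplyr::any_of(c(
      "year", "doy", "tree_id", "observed", "predicted", "residual"
    )))

  loo <- loo_uncertainty(drivers, target, config, extra_exclude = extra)
  weekly <- flag_legacy(daily, loo$bands)

  structure(
    list(
      daily = daily,
      weekly = weekly,
      bands = loo$bands,
      oob_score = fp$oob_score,
      loo_rmse = loo$loo_rmse,
      n_loo_fits = loo$n_fits,
      trained_years = sort(unique(train$year)),
      predict_years = sort(unique(predict_years)),
      config = config
    ),
    class = "legacy_analysis"
  )
}

#' @export
print.legacy_analysis <- function(x, ...) {
  g <- glance(x)
  cat("<legacy_analysis>\n")
  cat(sprintf(
    "  trained on %d years (%s excluded), predicted %s\n",
    length(x$trained_years),
    paste(x$config$post_drought_years, collapse = ", "),
    paste(x$predict_years, collapse = ", ")
  ))
  cat(sprintf(
    "  OOB pseudo-R2 = %.3f, LOO RMSE = %.3f (%d fits)\n",
    g$oob_score, g$loo_rmse, x$n_loo_fits
  ))
  cat(sprintf(
    "  weeks flagged: %d negative, %d positive of %d (%.1f%%)\n",
    g$n_negative, g$n_positive, g$n_weeks, 100 * g$flagged_fraction
  ))
  invisible(x)
}

#' Tidy the weekly legacy-detection results
#'
#' @param x A `legacy_analysis` object.
#' @param ... Unused.
#' @return The weekly tibble of residuals, bands and flags.
#' @exportS3Method generics::tidy
tidy.legacy_analysis <- function(x, ...) x$weekly

#' One-row summary of a legacy analysis
#'
#' @param x A `legacy_analysis` object.
#' @param ... Unused.
#' @return A one-row tibble: OOB score, LOO RMSE, week counts per flag and
#'   the flagged fraction.
#' @exportS3Method generics::glance
glance.legacy_analysis <- function(x, ...) {
  w <- x$weekly$flag
  w <- w[!is.na(w)]
  tibble(
    oob_score = x$oob_score,
    loo_rmse = x$loo_rmse,
    n_weeks = length(w),
    n_negative = sum(w == "negative"),
    n_positive = sum(w == "positive"),
    flagged_fraction = mean(w != "none")
  )
}
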