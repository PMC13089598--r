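# shared small fixture: 8-year scenario, GPP target
fixture <- local({
  cfg <- small_scenario(seed = 40)
  drv <- generate_drivers(cfg)
  fx <- generate_fluxes(drv, cfg)
  list(
    cfg = cfg, drv = drv, fx = fx,
    gpp = tibble::tibble(year = fx$year, doy = fx$doy, value = fx$GPP_true)
  )
})

fast_config <- function(...) {
  legacy_config(
    post_drought_years = fixture$cfg$post_drought_years,
    n_trees = 60, engine = "ranger", seed = 1, ...
  )
}

test_that("training assembly excludes post-drought years and incomplete rows", {
  mc <- fast_config()
  tgt <- fixture$gpp
  tgt$value[tgt$year == 2003 & tgt$doy == 50] <- NA
  tr <- assemble_training(fixture$drv, tgt, mc)
  expect_false(any(tr$year %in% 2008:2009))
  expect_false(any(tr$year == 2003 & tr$doy == 50))
  expect_true(all(c("SWC", "VPD", "SW_IN", "TA", "WS", "precip") %in% names(tr)))

  restricted <- assemble_training(
    fixture$drv, tgt, fast_config(train_end = 2005)
  )
  expect_true(all(restricted$year <= 2005))
  expect_error(
    assemble_training(fixture$drv, tgt, fast_config(train_end = 1999)),
    "empty training set"
  )
  with_month <- assemble_training(fixture$drv, tgt, fast_config(add_month = TRUE))
  expect_equal(with_month$month, month_of_doy(with_month$doy))
})

test_that("pooled sap-flow training has one row per tree-day with a value", {
  trees <- tidyr::expand_grid(
    tree_id = paste0("tree", 1:5), year = 2003:2010, doy = 1:365
  )
  set.seed(41)
  trees$value <- rnorm(nrow(trees))
  trees$value[sample(nrow(trees), 2000)] <- NA
  mc <- fast_config()
  tr <- assemble_training(fixture$drv, trees, mc)
  expected <- sum(!is.na(trees$value) & !trees$year %in% 2008:2009)
  expect_equal(nrow(tr), expected)
  expect_s3_class(tr$tree_id, "factor")
})

test_that("every fit refuses a leaked post-drought year", {
  mc <- fast_config()
  leaked <- dplyr::mutate(
    assemble_training(fixture$drv, fixture$gpp, mc),
    year = ifelse(dplyr::row_number() == 1, 2008L, year)
  )
  newdata <- leaked[1:5, ]
  expect_error(fit_predict(leaked, newdata, mc), "post-drought year in training mask")
})

test_that("a single-valued target is rejected as degenerate", {
  mc <- fast_config()
  tgt <- dplyr::mutate(fixture$gpp, value = 1)
  tr <- assemble_training(fixture$drv, tgt, mc)
  expect_error(fit_predict(tr, tr, mc), "degenerate target")
})

test_that("a noiseless driver-determined target is learned almost perfectly", {
  cfg <- small_scenario(
    seed = 42,
    response_params = list(GPP = list(noise_sd = 0))
  )
  drv <- generate_drivers(cfg)
  fx <- generate_fluxes(drv, cfg)
  tgt <- tibble::tibble(year = fx$year, doy = fx$doy, value = fx$GPP_true)
  mc <- legacy_config(
    post_drought_years = cfg$post_drought_years,
    n_trees = 100, engine = "ranger", seed = 2
  )
  fp <- fit_predict(
    assemble_training(drv, tgt, mc),
    dplyr::filter(droughtlegacy:::join_predictors(drv, tgt, mc), year %in% 2008:2009),
    mc
  )
  expect_gt(fp$oob_score, 0.95)
})

test_that("fits are reproducible under a fixed seed for both engines", {
  tr <- assemble_training(fixture$drv, fixture$gpp, fast_config())
  new <- tr[1:100, ]
  for (eng in c("ranger", "randomForest")) {
    mc <- legacy_config(
      post_drought_years = 2008:2009, n_trees = 60,
      engine = eng, seed = 3
    )
    p1 <- fit_predict(tr, new, mc)
    p2 <- fit_predict(tr, new, mc)
    expect_identical(p1$predictions, p2$predictions)
    expect_identical(p1$oob_score, p2$oob_score)
  }
})

test_that("the two forest engines agree on skill and predictions", {
  tr <- assemble_training(fixture$drv, fixture$gpp, fast_config())
  new <- dplyr::filter(
    droughtlegacy:::join_predictors(fixture$drv, fixture$gpp, fast_config()),
    year %in% 2008:2009
  )
  fits <- lapply(c("ranger", "randomForest"), function(eng) {
    mc <- legacy_config(
      post_drought_years = 2008:2009, n_trees = 150,
      engine = eng, seed = 4
    )
    fit_predict(tr, new, mc)
  })
  expect_lt(abs(fits[[1]]$oob_score - fits[[2]]$oob_score), 0.05)
  expect_gt(cor(fits[[1]]$predictions$predicted, fits[[2]]$predictions$predicted), 0.98)
})

test_that("tree-label permutation does not change pooled predictions", {
  set.seed(43)
  trees <- tidyr::expand_grid(
    tree_id = paste0("tree", 1:4), year = 2003:2010, doy = 1:365
  )
  base <- fixture$fx$GPP_true[match(
    paste(trees$year, trees$doy),
    paste(fixture$fx$year, fixture$fx$doy)
  )]
  trees$value <- base * rep(c(0.8, 0.9, 1.1, 1.2), each = 8 * 365)
  relabel <- c(tree1 = "treeD", tree2 = "treeC", tree3 = "treeB", tree4 = "treeA")
  trees2 <- dplyr::mutate(trees, tree_id = unname(relabel[tree_id]))

  fit_both <- function(eng) {
    mc <- legacy_config(
      post_drought_years = 2008:2009, n_trees = 60, engine = eng, seed = 5
    )
    lapply(list(trees, trees2), function(tg) {
      tr <- assemble_training(fixture$drv, tg, mc)
      fit_predict(tr, tr, mc)$predictions$predicted
    })
  }
  # the conventional engine orders categories by mean response: exact
  rf <- fit_both("randomForest")
  expect_equal(rf[[1]], rf[[2]], tolerance = 1e-12)
  # ranger partitions category subsets; its RNG stream depends on level
  # order, so invariance is statistical rather than bitwise
  rg <- fit_both("ranger")
  expect_gt(cor(rg[[1]], rg[[2]]), 0.995)
  expect_lt(mean(abs(rg[[1]] - rg[[2]])), 0.05 * sd(rg[[1]]))
})

test_that("leave-one-out uncertainty fits one model per non-post-drought year", {
  mc <- fast_config()
  loo <- loo_uncertainty(fixture$drv, fixture$gpp, mc)
  expect_equal(loo$n_fits, 6) # 8 years minus 2 post-drought
  expect_setequal(unique(loo$residuals$year), setdiff(2003:2010, 2008:2009))
  expect_true(all(loo$bands$p5 <= loo$bands$p25))
  expect_true(all(loo$bands$p25 <= loo$bands$p75))
  expect_true(all(loo$bands$p75 <= loo$bands$p95))
  expect_equal(nrow(loo$bands), 52)
  expect_true(is.finite(loo$loo_rmse) && loo$loo_rmse > 0)

  few <- legacy_config(post_drought_years = 2004:2010, seed = 1)
  expect_error(loo_uncertainty(fixture$drv, fixture$gpp, few), "need >= 5")
})

test_that("flags follow the strict band rule", {
  bands <- tibble::tibble(
    week = 1:52, p5 = -1, p25 = -0.5, p75 = 0.5, p95 = 1, n_years = 6
  )
  daily <- tibble::tibble(
    year = 2008,
    doy = 1:21,
    residual = rep(c(1, -1.2, 0), each = 7) # on the edge, below p5, inside
  )
  fl <- flag_legacy(daily, bands)
  expect_equal(fl$flag, c("none", "negative", "none"))
  expect_equal(fl$weekly_residual, c(1, -1.2, 0))
})

test_that("the full analysis object is consistent and variants only change the mask", {
  mc <- fast_config()
  res <- run_legacy_analysis(fixture$drv, fixture$gpp, mc)
  expect_s3_class(res, "legacy_analysis")
  expect_setequal(res$trained_years, setdiff(2003:2010, 2008:2009))
  expect_setequal(unique(res$daily$year), 2008:2009)
  expect_equal(res$daily$residual, res$daily$observed - res$daily$predicted)
  g <- glance(res)
  expect_equal(g$n_weeks, 104)
  expect_equal(g$n_negative + g$n_positive, round(g$flagged_fraction * g$n_weeks))
  expect_s3_class(tidy(res), "tbl_df")

  half <- run_legacy_analysis(fixture$drv, fixture$gpp, fast_config(train_end = 2006))
  expect_setequal(half$trained_years, 2003:2006)
  expect_setequal(unique(half$daily$year), 2008:2009)
  expect_identical(half$daily[c("year", "doy")], res$daily[c("year", "doy")])

  # hindcasting the drought year excludes it from training and the LOO pool
  hind <- run_legacy_analysis(fixture$drv, fixture$gpp, mc, predict_years = 2007)
  expect_false(2007 %in% hind$trained_years)
  expect_setequal(unique(hind$daily$year), 2007)
  expect_equal(hind$n_loo_fits, 5)
})

test_that("autoplot returns a ggplot of the residual envelope", {
  mc <- fast_config()
  res <- run_legacy_analysis(fixture$drv, fixture$gpp, mc)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
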