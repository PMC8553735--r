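test_that("scaling fits recover exact lines and reject degenerate input", {
  x <- seq(1, 20)
  f <- fit_scaling(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r, 1)

  fc <- fit_scaling(x, rep(5, 20))
  expect_equal(fc$slope, 0)
  expect_equal(fc$intercept, 5)

  expect_error(fit_scaling(1:2, 1:2), "at least 3 pairs")
  expect_error(fit_scaling(rep(1, 5), 1:5), "degenerate predictor")
  # missing pairs are dropped before the count
  expect_error(fit_scaling(c(1, 2, NA, NA), c(1, 2, 3, 4)),
               "at least 3 pairs")
})

test_that("noisy scaling fits fall within classical OLS error bounds", {
  set.seed(21)
  x <- runif(200, 5, 40)
  y <- 0.8 * x + 3 + rnorm(200, 0, 1)
  f <- fit_scaling(x, y)
  sm <- summary(lm(y ~ x))$coefficients
  expect_lt(abs(f$slope - 0.8), 3 * sm["x", "Std. Error"])
  expect_lt(abs(f$intercept - 3), 3 * sm["(Intercept)", "Std. Error"])
})

test_that("applied scalings clip, round half-up and cap count predictions", {
  fn <- structure(list(metric = NA_character_, scenario = NA, slope = 2,
                       intercept = 1, n = 10, r = 1),
                  class = "aq_scaling")
  expect_equal(apply_scaling(fn, 5, 2018), 11)
  fn_neg <- fn; fn_neg$slope <- -2
  expect_equal(apply_scaling(fn_neg, 5, 2018), 0)

  fn_cnt <- fn; fn_cnt$metric <- "pm10_days_gt_50"
  expect_equal(apply_scaling(fn_cnt, 2.2, 2018), 5)   # 5.4 -> 5
  expect_equal(apply_scaling(fn_cnt, 2.25, 2018), 6)  # 5.5 rounds up
  expect_equal(apply_scaling(fn_cnt, 250, 2018), 365) # capped
  expect_equal(apply_scaling(fn_cnt, 250, 2020), 366) # leap-year cap
  fn_h <- fn; fn_h$metric <- "no2_hours_gt_200"
  expect_equal(apply_scaling(fn_h, 1e5, 2018), 8760)

  fn_bad <- fn; fn_bad$n <- 2
  expect_error(apply_scaling(fn_bad, 1, 2018), "unusable")
})

test_that("sub-daily relations respect the anchor map and degenerate targets", {
  a <- seq(30, 60, length.out = 30)
  t <- 1.3 * a + 5
  f <- fit_subdaily(a, t, "o3_dailymax_avg")
  expect_equal(f$anchor, "o3_avg")
  expect_equal(f$slope, 1.3)
  expect_equal(f$intercept, 5)

  f0 <- fit_subdaily(a, rep(0, 30), "no2_hours_gt_200")
  expect_equal(f0$slope, 0)
  expect_equal(f0$intercept, 0)
  expect_equal(apply_scaling(f0, 35, 2018), 0)

  expect_error(fit_subdaily(a, t, "pm25_avg"), "not a sub-daily metric")
})

make_fits <- function(slope = 1, intercept = 0) {
  sc <- lapply(AQ_RASTER_METRICS, function(m) structure(
    list(metric = m, scenario = "average", slope = slope,
         intercept = intercept, n = 10, r = 1), class = "aq_scaling"))
  names(sc) <- AQ_RASTER_METRICS
  sd <- lapply(names(AQ_SUBDAILY_ANCHOR), function(m) structure(
    list(metric = m, scenario = "average", slope = slope,
         intercept = intercept, n = 10, r = 1,
         anchor = AQ_SUBDAILY_ANCHOR[[m]]),
    class = c("aq_subdaily", "aq_scaling")))
  names(sd) <- names(AQ_SUBDAILY_ANCHOR)
  list(scalings = sc, subdaily = sd)
}

test_that("gap filling fills only the holes and flags provenance", {
  fits <- make_fits()
  full <- setNames(seq(10, 20, length.out = 11), AQ_METRICS)
  rea <- setNames(rep(99, 7), AQ_RASTER_METRICS)

  gf <- gapfill_unit_year(full, rea, fits$scalings, fits$subdaily, 2018)
  expect_identical(gf$values, full)
  expect_true(all(gf$provenance == "observed"))

  none <- setNames(rep(NA_real_, 11), AQ_METRICS)
  gf2 <- gapfill_unit_year(none, rea, fits$scalings, fits$subdaily, 2018)
  expect_true(all(gf2$provenance == "reanalysis-derived"))
  expect_equal(gf2$values[["no2_avg"]], 99)
  # sub-daily metric derived from the gap-filled anchor, count rules applied
  expect_equal(gf2$values[["no2_hours_gt_200"]], 99)
  expect_equal(gf2$values[["o3_dailymax_avg"]], 99)

  mixed <- none
  mixed[c("no2_avg", "no2_hours_gt_200")] <- c(25, 3)
  gf3 <- gapfill_unit_year(mixed, rea, fits$scalings, fits$subdaily, 2018)
  expect_equal(unname(gf3$provenance[c("no2_avg", "no2_hours_gt_200")]),
               c("observed", "observed"))
  expect_equal(unname(gf3$provenance[["pm10_avg"]]), "reanalysis-derived")
  expect_equal(gf3$values[["no2_avg"]], 25)

  expect_error(
    gapfill_unit_year(none, rea[-1], fits$scalings, fits$subdaily, 2018),
    "incomplete field")
})

test_that("generator affine links are recovered through the full raster branch", {
  w <- aligned_world()
  rea <- reanalysis_unit_values(
    lapply(w$rasters, function(r) r[["2018"]]), w$units)
  for (m in AQ_RASTER_METRICS[AQ_METRIC_KIND[AQ_RASTER_METRICS] == "mean"]) {
    p <- AQ_METRIC_POLLUTANT[[m]]
    lk <- w$links[w$links$pollutant == p, ]
    tr <- w$truth[w$truth$pollutant == p & w$truth$year == 2018, ]
    j <- dplyr::inner_join(tr, rea[rea$metric == m, ], by = "nuts_code")
    f <- fit_scaling(j$truth, j$value)
    expect_lt(abs(f$slope - lk$slope) / lk$slope, 1e-6)
    expect_lt(abs(f$intercept - lk$intercept) / abs(lk$intercept), 1e-6)
  }
})

test_that("gap-filling a complete table is the identity with one flag per metric", {
  w <- small_world()
  sm <- station_metrics_table(
    w$stations, function(sid, p, y) world_series(w, sid, p, y), 2018)
  obs <- aggregate_units(sm, w$stations, w$units, "average",
                         w$ratification)
  rea <- reanalysis_unit_values(
    lapply(w$rasters, function(r) r[["2018"]]), w$units)
  filled <- gapfill_table(obs, rea)
  expect_false(anyNA(filled$value))
  expect_true(all(filled$provenance %in%
                    c("observed", "reanalysis-derived")))
  # observed values pass through untouched
  j <- dplyr::inner_join(
    filled[filled$provenance == "observed", ],
    obs, by = c("nuts_code", "year", "metric"),
    suffix = c("_filled", "_obs"))
  expect_equal(j$value_filled, j$value_obs)
  # idempotence: refilling the complete table changes nothing
  obs2 <- filled[, c("nuts_code", "year", "scenario", "metric", "value",
                     "station_types", "ratified")]
  filled2 <- gapfill_table(obs2, rea)
  expect_equal(filled2$value, filled$value)
  expect_true(all(filled2$provenance == "observed"))
})

test_that("regional-average baseline fills from the region mean", {
  units <- generate_units(4, c(lon_min = 0, lon_max = 2,
                               lat_min = 0, lat_max = 2), n_regions = 2)
  obs <- tidyr::expand_grid(nuts_code = units$nuts_code, year = 2018L,
                            metric = "no2_avg")
  obs$scenario <- "average"
  expect_equal(units$region, c("DER01", "DER01", "DER02", "DER02"))
  # a region with no observations at all stays unfilled
  obs$value <- c(10, 20, NA, NA)
  got <- baseline_regional(obs, units)
  expect_true(all(is.na(got$value[3:4])))
  expect_true(all(is.na(got$provenance[3:4])))
  # a gap inside a partly observed region gets the region mean
  obs2 <- obs
  obs2$value <- c(10, NA, 30, 40)
  got2 <- baseline_regional(obs2, units)
  expect_equal(got2$value[2], 10)
  expect_equal(got2$provenance[2], "regional-average")
  expect_equal(got2$provenance[1], "observed")
  # fully observed region unchanged
  expect_equal(got2$value[3:4], c(30, 40))
})

test_that("nearest-neighbour baseline copies the closest donor, ties to lower code", {
  units <- generate_units(4, c(lon_min = 0, lon_max = 4,
                               lat_min = 0, lat_max = 1))
  obs <- tidyr::expand_grid(nuts_code = units$nuts_code, year = 2018L,
                            metric = "no2_avg")
  obs$scenario <- "average"
  # single donor: everyone copies it
  obs$value <- c(50, NA, NA, NA)
  got <- baseline_nearest(obs, units)
  expect_equal(got$value, rep(50, 4))
  expect_equal(got$provenance[2:4], rep("nearest-neighbour", 3))
  # equidistant donors on both sides: lower code wins
  obs$value <- c(10, NA, 30, NA)   # DE002 is equidistant to DE001/DE003
  got2 <- baseline_nearest(obs, units)
  expect_equal(got2$value[2], 10)
  # the city-neighbour artifact: an unmonitored unit adjacent to a
  # monitored "city" unit inherits the city's exposure value verbatim
  obs$value <- c(NA, 45, NA, 12)
  got3 <- baseline_nearest(obs, units)
  expect_equal(got3$value[1], 45)
})
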