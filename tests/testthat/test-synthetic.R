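test_that("unit generation tiles the domain exactly", {
  box <- c(lon_min = 0, lon_max = 3, lat_min = 0, lat_max = 2)

  u1 <- generate_units(1, box)
  expect_equal(nrow(u1), 1L)
  expect_equal(unname(unlist(u1[1, c("lon_min", "lon_max",
                                     "lat_min", "lat_max")])),
               unname(box[c("lon_min", "lon_max", "lat_min", "lat_max")]))

  u6 <- generate_units(6, box)
  areas <- (u6$lon_max - u6$lon_min) * (u6$lat_max - u6$lat_min)
  expect_equal(areas, rep(6 / 6, 6))     # domain area 6, equal cells

  u402 <- generate_units(402)
  expect_equal(nrow(u402), 402L)
  expect_equal(length(unique(u402$nuts_code)), 402L)
  dom <- attr(u402, "domain")
  dom_area <- (dom[["lon_max"]] - dom[["lon_min"]]) *
    (dom[["lat_max"]] - dom[["lat_min"]])
  expect_equal(sum((u402$lon_max - u402$lon_min) *
                     (u402$lat_max - u402$lat_min)), dom_area)

  # a prime count still tiles (ragged rows), covering the full area
  u7 <- generate_units(7, box)
  expect_equal(sum((u7$lon_max - u7$lon_min) *
                     (u7$lat_max - u7$lat_min)), 6)
  expect_error(generate_units(3, c(lon_min = 1, lon_max = 1,
                                   lat_min = 0, lat_max = 1)),
               "degenerate")
})

test_that("interior points resolve to exactly one unit", {
  u <- generate_units(17, c(lon_min = 0, lon_max = 5,
                            lat_min = 0, lat_max = 4))
  set.seed(2)
  lon <- runif(500, 0.001, 4.999)
  lat <- runif(500, 0.001, 3.999)
  idx <- locate_points(lon, lat, u)
  ok <- lon >= u$lon_min[idx] & lon <= u$lon_max[idx] &
    lat >= u$lat_min[idx] & lat <= u$lat_max[idx]
  expect_true(all(ok))
})

test_that("station placement hits the requested unit coverage", {
  u <- generate_units(50, c(lon_min = 0, lon_max = 10,
                            lat_min = 0, lat_max = 10))
  for (seed in 1:20) {
    st <- generate_stations(u, coverage = c(NO2 = 0.5), seed = seed)
    meas <- attr(st, "measurements")
    bg <- st$station_id[st$type == "background"]
    covered <- unique(st$nuts_code[st$station_id %in%
                                     intersect(bg, meas$station_id)])
    expect_lte(abs(length(covered) - 25), 3)
    expect_true(all(st$lon >= 0 & st$lon <= 10))
  }
  expect_error(generate_stations(u[0, ], c(NO2 = 0.5)), "no units")
})

test_that("full coverage monitors every unit", {
  u <- generate_units(9, c(lon_min = 0, lon_max = 3,
                           lat_min = 0, lat_max = 3))
  st <- generate_stations(u, coverage = c(NO2 = 1), seed = 1)
  expect_setequal(unique(st$nuts_code[st$type == "background"]),
                  u$nuts_code)
})

test_that("world generation is deterministic in the seed", {
  cfg <- aq_config(n_units = 6L, years = 2018L,
                   coverage = c(NO2 = 0.5, NO = 0.5, O3 = 0.5,
                                PM10 = 0.5, "PM2.5" = 0.5), seed = 99L)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$stations, w2$stations)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$rasters$NO2$`2018`$values,
                   w2$rasters$NO2$`2018`$values)
  sid <- w1$measurements$station_id[1]
  p <- w1$measurements$pollutant[1]
  expect_identical(world_series(w1, sid, p, 2018)$values,
                   world_series(w2, sid, p, 2018)$values)
})

test_that("noiseless flat-factor series reproduce the truth value exactly", {
  s <- generate_hourly_series("NO2", 2018, 23.5, noise_sd = 0,
                              missing_fraction = 0, seasonal_amp = 0,
                              diurnal_amp = 0, episode_sd = 0)
  expect_equal(mean(s$values), 23.5)
  expect_true(all(s$values == 23.5))
  # with shape factors on, the noiseless annual mean is still the truth
  s2 <- generate_hourly_series("O3", 2018, 50, noise_sd = 0,
                               missing_fraction = 0, seed = 4)
  expect_equal(mean(s2$values, na.rm = TRUE), 50, tolerance = 1e-10)
  expect_error(generate_hourly_series("NO2", 2018, -1), "negative")
})

test_that("requested missingness defeats the data-capture rule downstream", {
  s <- generate_hourly_series("NO2", 2018, 20, missing_fraction = 0.25,
                              seed = 5)
  expect_equal(coverage(s), 0.75, tolerance = 1e-3)
  expect_true(is.na(annual_mean(s)))
})

test_that("synthetic rasters honour the affine link and 3-hourly layout", {
  u <- generate_units(4, c(lon_min = 0, lon_max = 3,
                           lat_min = 0, lat_max = 3))
  r <- generate_rasters(u, rep(10, 4), "NO2", 2018,
                        link = list(slope = 1, intercept = 0, noise_sd = 0),
                        grid = aq_grid(attr(u, "domain"), 0.75),
                        seasonal_amp = 0, episode_sd = 0)
  expect_equal(dim(r$values)[3], 8 * 365)
  expect_true(all(r$values == 10))

  r2 <- generate_rasters(u, c(10, 12, 14, 16), "NO2", 2018,
                         link = list(slope = 0.8, intercept = 3,
                                     noise_sd = 0),
                         grid = aq_grid(attr(u, "domain"), 0.75),
                         seasonal_amp = 0, episode_sd = 0)
  # units are 1.5 x 1.5 deg = 2 x 2 coarse cells: clipping is exact
  vec <- vectorize(cell_annual_metrics(list(NO2 = to_daily(r2))), u)
  got <- vec$value[vec$metric == "no2_avg"][match(u$nuts_code,
                                                  vec$nuts_code[vec$metric ==
                                                                  "no2_avg"])]
  expect_equal(got, 0.8 * c(10, 12, 14, 16) + 3, tolerance = 1e-12)

  small_grid <- list(lon = 0.375, lat = 0.375, res = 0.75)
  expect_error(
    generate_rasters(u, rep(10, 4), "NO2", 2018,
                     link = list(slope = 1, intercept = 0, noise_sd = 0),
                     grid = small_grid),
    "domain mismatch")
})

test_that("world inputs round-trip through their text formats", {
  w <- small_world()
  dir <- withr::local_tempdir()
  write_world(w, dir, years = 2018, write_hourly = FALSE,
              write_rasters = FALSE)
  st <- read_stations_csv(file.path(dir, "stations.csv"))
  expect_equal(nrow(st), nrow(w$stations))
  u <- read_units_geojson(file.path(dir, "units.geojson"))
  expect_equal(u$nuts_code, w$units$nuts_code)
  expect_equal(u$lon_min, w$units$lon_min)

  r <- w$rasters$NO2$`2018`
  rp <- withr::local_tempfile(fileext = ".csv")
  write_raster_csv(r, rp)
  r2 <- read_raster_csv(rp, "NO2", 2018, r$res)
  expect_equal(r2$values, r$values)
  expect_equal(r2$lon, r$lon)
})
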