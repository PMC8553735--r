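test_that("annual metrics match the brute-force oracle on random series", {
  set.seed(101)
  for (rep in 1:6) {
    year <- sample(c(2015, 2016), 1)   # mix leap and non-leap
    vals <- list(
      NO2 = random_hourly_values(year, 35),
      NO = random_hourly_values(year, 12),
      O3 = random_hourly_values(year, 60, missing_fraction = 0.1),
      PM10 = random_hourly_values(year, 30),
      "PM2.5" = random_hourly_values(year, 15)
    )
    series <- lapply(names(vals), function(p)
      hourly_series(vals[[p]], p, year))
    names(series) <- names(vals)
    got <- unlist(station_metric_vector(series, year))
    want <- oracle_metric_vector(vals, year)
    counts <- AQ_METRIC_KIND[AQ_METRICS] %in% c("count_hours",
                                                "count_days")
    expect_identical(unname(got[counts]), unname(want[counts]))
    expect_equal(unname(got[!counts]), unname(want[!counts]),
                 tolerance = 1e-12)
  }
})

test_that("the 80 percent data-capture rule is a sharp cutoff", {
  year <- 2018
  H <- hours_in_year(year)
  v <- rep(42, H)
  at80 <- v; at80[seq_len(H - 7008)] <- NA   # 7008/8760 = 0.8 exactly
  s80 <- hourly_series(at80, "NO2", year)
  expect_equal(coverage(s80), 0.8)
  expect_equal(annual_mean(s80), 42)
  expect_equal(count_hourly_exceedances(s80, 200), 0L)

  at79 <- v; at79[seq_len(ceiling(0.21 * H))] <- NA
  s79 <- hourly_series(at79, "NO2", year)
  expect_lt(coverage(s79), 0.8)
  expect_true(is.na(annual_mean(s79)))
  expect_true(is.na(count_hourly_exceedances(s79, 200)))
  mv <- station_metric_vector(list(NO2 = s79), year)
  expect_true(all(is.na(unlist(mv))))
})

test_that("full coverage gives coverage 1 and a calendar-checked length", {
  s <- flat_series(10, year = 2018)
  expect_equal(coverage(s), 1)
  expect_error(hourly_series(rep(1, 8760), "NO2", 2016),
               "calendar mismatch")
  expect_equal(length(flat_series(1, year = 2012)$values), 8784L)
})

test_that("daily aggregation applies the 18-of-24-hour validity rule", {
  year <- 2018
  v <- rep(80, hours_in_year(year))
  s <- hourly_series(v, "PM10", year)
  expect_equal(daily_aggregate(s, "mean")[1], 80)

  v2 <- v
  v2[1:24] <- c(0:23)                    # day 1: hours equal their index
  v2[25:36] <- NA                        # day 2: only 12 valid hours
  s2 <- hourly_series(v2, "PM10", year)
  dmax <- daily_aggregate(s2, "max")
  expect_equal(dmax[1], 23)
  expect_true(is.na(dmax[2]))
  dmean <- daily_aggregate(s2, "mean")
  expect_true(is.na(dmean[2]))
  # 18 valid hours is enough
  v3 <- v; v3[25:30] <- NA
  expect_false(is.na(daily_aggregate(hourly_series(v3, "PM10", year),
                                     "mean")[2]))
})

test_that("daily exceedance counts use strict thresholds", {
  year <- 2018
  nd <- days_in_year(year)
  s130 <- flat_series(130, "O3", year)
  expect_equal(count_daily_exceedances(daily_aggregate(s130, "mean"), 120),
               nd)
  s45 <- flat_series(45, "PM10", year)
  expect_equal(count_daily_exceedances(daily_aggregate(s45, "mean"), 50), 0L)
  # exactly at the threshold does not count
  s50 <- flat_series(50, "PM10", year)
  expect_equal(count_daily_exceedances(daily_aggregate(s50, "mean"), 50), 0L)
  # 7 elevated days
  v <- rep(30, hours_in_year(year))
  v[1:(7 * 24)] <- 55
  s7 <- hourly_series(v, "PM10", year)
  expect_equal(count_daily_exceedances(daily_aggregate(s7, "mean"), 50), 7L)
})

test_that("running 8-hour means match the window-enumeration oracle", {
  year <- 2018
  v <- rep(50, hours_in_year(year))
  v[1000:1007] <- 100                    # one elevated 8-hour block
  s <- hourly_series(v, "O3", year)
  expect_equal(max_8h_daily(s), oracle_max8h_daily(v))

  # constant series: every valid window mean equals the constant
  sc <- flat_series(77, "O3", year)
  d8 <- max_8h_daily(sc)
  expect_true(all(d8[!is.na(d8)] == 77))
  expect_equal(max(d8, na.rm = TRUE), 77)
})

test_that("o3_max_8h never exceeds o3_max_1h and o3_avg never exceeds o3_dailymax_avg", {
  set.seed(7)
  for (rep in 1:5) {
    v <- random_hourly_values(2018, 60, missing_fraction = 0.1)
    mv <- station_metric_vector(list(O3 = hourly_series(v, "O3", 2018)),
                                2018)
    expect_lte(mv$o3_max_8h, mv$o3_max_1h)
    expect_lte(mv$o3_avg, mv$o3_dailymax_avg)
  }
})

test_that("adding missing hours never increases coverage", {
  set.seed(8)
  v <- random_hourly_values(2018, 40, missing_fraction = 0.1)
  s <- hourly_series(v, "NO2", 2018)
  for (rep in 1:5) {
    v[sample.int(length(v), 200)] <- NA
    s2 <- hourly_series(v, "NO2", 2018)
    expect_lte(coverage(s2), coverage(s))
    s <- s2
  }
})

test_that("a station measuring one pollutant yields only that pollutant's metrics", {
  mv <- station_metric_vector(list("PM2.5" = flat_series(14, "PM2.5", 2018)),
                              2018)
  expect_equal(mv$pm25_avg, 14)
  expect_true(all(is.na(unlist(mv[setdiff(AQ_METRICS, "pm25_avg")]))))
  expect_error(station_metric_vector(list(SO2 = flat_series(1)), 2018),
               "unknown pollutant")
})

test_that("metrics are invariant to hourly record order in CSV input", {
  set.seed(9)
  v <- random_hourly_values(2018, 40, missing_fraction = 0.2)
  s <- hourly_series(v, "NO2", 2018, "ST00001")
  path <- withr::local_tempfile(fileext = ".csv")
  write_hourly_csv(list(s), path)
  df <- readr::read_csv(path, show_col_types = FALSE)
  df <- df[sample.int(nrow(df)), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path2)
  s2 <- read_hourly_csv(path2, 2018)[["ST00001.NO2"]]
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_equal(unlist(station_metric_vector(list(NO2 = s2), 2018)),
               unlist(station_metric_vector(list(NO2 = s), 2018)),
               tolerance = 1e-12)
})

test_that("traffic and industrial stations are excluded from the metric table", {
  stations <- tibble::tibble(
    station_id = c("A", "B", "C"),
    type = c("background", "traffic", "industrial"),
    area_class = "urban"
  )
  get_series <- function(sid, p, y) {
    if (p == "NO2") flat_series(20, "NO2", y) else NULL
  }
  tab <- station_metrics_table(stations, get_series, 2018)
  expect_equal(tab$station_id, "A")
  expect_equal(tab$no2_avg, 20)
})
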