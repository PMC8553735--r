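# Cached fixture worlds shared across test files (built once per run).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small noisy world for structural tests
small_world <- function() {
  memo("small", generate_world(aq_config(
    n_units = 12L, years = 2018:2019,
    coverage = c(NO2 = 0.5, NO = 0.5, O3 = 0.5, PM10 = 0.5, "PM2.5" = 0.4),
    seed = 42L
  )))
}

# noiseless world whose 3x3-degree units align with the 0.75-degree grid,
# so cell-center clipping is exact and the affine link is recoverable to
# machine precision
aligned_world <- function() {
  memo("aligned", generate_world(aq_config(
    n_units = 16L, years = 2018L,
    domain = c(lon_min = 0, lon_max = 12, lat_min = 0, lat_max = 12),
    coverage = c(NO2 = 0.5, NO = 0.5, O3 = 0.5, PM10 = 0.5, "PM2.5" = 0.5),
    noiseless = TRUE, seed = 11L
  )))
}

# one flat full-coverage hourly series
flat_series <- function(value, pollutant = "NO2", year = 2018) {
  generate_hourly_series(pollutant, year, value, noise_sd = 0,
                         missing_fraction = 0, seasonal_amp = 0,
                         diurnal_amp = 0, episode_sd = 0)
}

# constant-field metric raster on an n x n coarse grid
constant_metric_raster <- function(value, n = 2, res = 0.75, year = 2018,
                                   metric = "no2_avg") {
  structure(
    list(lon = res * (seq_len(n) - 0.5), lat = res * (seq_len(n) - 0.5),
         res = res, year = year, metric = metric,
         values = matrix(value, n, n)),
    class = "aq_metric_raster"
  )
}

make_unit_metrics <- function(values, classes, metric = "no2_avg",
                              year = 2018) {
  # one unit, one station per row, a single metric populated
  n <- length(values)
  sm <- tibble::tibble(station_id = sprintf("S%02d", seq_len(n)),
                       year = year)
  for (m in AQ_METRICS) sm[[m]] <- NA_real_
  sm[[metric]] <- values
  stations <- tibble::tibble(
    station_id = sm$station_id, type = "background",
    area_class = classes, lon = 0.5, lat = 0.5
  )
  units <- generate_units(1, c(lon_min = 0, lon_max = 1,
                               lat_min = 0, lat_max = 1))
  list(sm = sm, stations = stations, units = units)
}
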