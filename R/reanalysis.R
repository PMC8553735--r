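#' Average a 3-hourly raster stack to daily fields
#'
#' Per-cell mean of each day's timesteps. The stack must hold complete
#' days (a fixed number of timesteps per day for the whole year).
#'
#' @param stack an `aq_raster` (see [generate_rasters()]).
#' @param n_per_day timesteps per day (default 8, i.e. 3-hourly).
#' @return object of class `aq_daily_raster`: `lon`, `lat`, `res`, `year`,
#'   `values` array `[lon, lat, day]`, `pollutant`.
#' @export
to_daily <- function(stack, n_per_day = 8L) {
  stopifnot(inherits(stack, "aq_raster"))
  nt <- dim(stack$values)[3]
  nd <- days_in_year(stack$year)
  if (nt != nd * n_per_day) {
    stop("incomplete day: ", nt, " timesteps is not ", n_per_day,
         " per day over ", nd, " days", call. = FALSE)
  }
  nlon <- length(stack$lon); nlat <- length(stack$lat)
  m <- matrix(stack$values, nrow = nlon * nlat)   # cells x timesteps
  daily <- matrix(NA_real_, nlon * nlat, nd)
  for (d in seq_len(nd)) {
    idx <- ((d - 1L) * n_per_day + 1L):(d * n_per_day)
    daily[, d] <- rowMeans(m[, idx, drop = FALSE])
  }
  structure(
    list(lon = stack$lon, lat = stack$lat, res = stack$res,
         year = stack$year, pollutant = stack$pollutant,
         values = array(daily, dim = c(nlon, nlat, nd))),
    class = "aq_daily_raster"
  )
}

# single-layer metric raster container
metric_raster <- function(values, template, metric) {
  structure(
    list(lon = template$lon, lat = template$lat, res = template$res,
         year = template$year, metric = metric, values = values),
    class = "aq_metric_raster"
  )
}

#' Per-cell annual metrics from daily rasters
#'
#' Computes, for each grid cell, every metric with daily-or-coarser time
#' resolution available from the supplied pollutants: the five annual
#' means and the PM10 > 50 and O3 > 120 daily exceedance-day counts
#' (strict inequalities, identical semantics to the station metrics).
#'
#' @param daily_by_pollutant named list of `aq_daily_raster` objects.
#' @return named list of `aq_metric_raster` (names in
#'   `AQ_RASTER_METRICS`).
#' @export
cell_annual_metrics <- function(daily_by_pollutant) {
  out <- list()
  mean_metric <- c(NO2 = "no2_avg", NO = "no_avg", PM10 = "pm10_avg",
                   "PM2.5" = "pm25_avg", O3 = "o3_avg")
  for (p in names(daily_by_pollutant)) {
    dr <- daily_by_pollutant[[p]]
    stopifnot(inherits(dr, "aq_daily_raster"))
    nd <- dim(dr$values)[3]
    stopifnot(nd == days_in_year(dr$year))
    avg <- rowMeans(dr$values, dims = 2L)
    out[[mean_metric[[p]]]] <- metric_raster(avg, dr, mean_metric[[p]])
    if (p == "PM10") {
      cnt <- rowSums(dr$values > AQ_THRESHOLDS[["PM10_daily"]], dims = 2L)
      out[["pm10_days_gt_50"]] <- metric_raster(cnt, dr, "pm10_days_gt_50")
    }
    if (p == "O3") {
      cnt <- rowSums(dr$values > AQ_THRESHOLDS[["O3_daily"]], dims = 2L)
      out[["o3_days_gt_120"]] <- metric_raster(cnt, dr, "o3_days_gt_120")
    }
  }
  out
}

#' Upscale a metric raster by value replication
#'
#' Refines the grid from the coarse resolution to `target_res` (default
#' 0.01 degrees), each fine cell taking exactly the value of its parent
#' coarse cell — no interpolation. The replication factor must be an
#' integer.
#'
#' @param raster an `aq_metric_raster`.
#' @param target_res fine resolution in degrees.
#' @return an `aq_metric_raster` on the fine grid.
#' @export
upscale <- function(raster, target_res = 0.01) {
  f <- raster$res / target_res
  if (abs(f - round(f)) > 1e-9) {
    stop("non-integer replication factor: ", raster$res, " / ", target_res,
         call. = FALSE)
  }
  f <- as.integer(round(f))
  nlon <- length(raster$lon); nlat <- length(raster$lat)
  fine_vals <- raster$values[rep(seq_len(nlon), each = f),
                             rep(seq_len(nlat), each = f), drop = FALSE]
  lon0 <- raster$lon[1] - raster$res / 2
  lat0 <- raster$lat[1] - raster$res / 2
  structure(
    list(lon = lon0 + target_res * (seq_len(nlon * f) - 0.5),
         lat = lat0 + target_res * (seq_len(nlat * f) - 0.5),
         res = target_res, year = raster$year, metric = raster$metric,
         values = fine_vals),
    class = "aq_metric_raster"
  )
}

#' Zonal mean of a fine raster over one unit
#'
#' Mean of the fine-cell values whose cell centers fall inside the unit
#' rectangle. At 0.01-degree resolution this approximates the exact
#' area-weighted mean to within the boundary-cell fraction. Cell centers
#' exactly on the unit's upper/right edge belong to the neighbouring unit
#' (half-open membership), except at the raster's outer extent, so that
#' units partition the cells with no double counting.
#'
#' @param fine an `aq_metric_raster` at fine resolution.
#' @param unit one-row slice of an `aq_units` tibble.
#' @return scalar zonal mean.
#' @export
clip_unit <- function(fine, unit) {
  eps <- 1e-9
  lon_hi_closed <- unit$lon_max >= max(fine$lon) - eps
  lat_hi_closed <- unit$lat_max >= max(fine$lat) - eps
  sel_lon <- which(fine$lon >= unit$lon_min - eps &
                     (fine$lon < unit$lon_max - eps |
                        (lon_hi_closed & fine$lon <= unit$lon_max + eps)))
  sel_lat <- which(fine$lat >= unit$lat_min - eps &
                     (fine$lat < unit$lat_max - eps |
                        (lat_hi_closed & fine$lat <= unit$lat_max + eps)))
  if (!length(sel_lon) || !length(sel_lat)) {
    stop("unit below resolution: ", unit$nuts_code, call. = FALSE)
  }
  mean(fine$values[sel_lon, sel_lat])
}

#' Vectorize metric rasters to unit values
#'
#' Upscales each daily-or-coarser metric raster to the fine resolution and
#' clips it to every unit, yielding one value per unit x metric x year —
#' for all units, monitored or not.
#'
#' @param metric_rasters named list from [cell_annual_metrics()].
#' @param units an `aq_units` tibble.
#' @param fine_res fine resolution in degrees (default 0.01).
#' @return tibble `nuts_code`, `metric`, `year`, `value`.
#' @export
vectorize <- function(metric_rasters, units, fine_res = 0.01) {
  rows <- list()
  for (m in names(metric_rasters)) {
    fine <- upscale(metric_rasters[[m]], fine_res)
    vals <- vapply(seq_len(nrow(units)),
                   function(i) clip_unit(fine, units[i, ]),
                   numeric(1))
    rows[[m]] <- tibble::tibble(
      nuts_code = units$nuts_code, metric = m,
      year = metric_rasters[[m]]$year, value = vals
    )
  }
  dplyr::bind_rows(rows)
}

#' Full raster branch for one world-year
#'
#' 3-hourly stacks to daily fields to per-cell annual metrics to vectorized
#' unit values, for every pollutant.
#'
#' @param rasters_by_pollutant named list of `aq_raster` for one year.
#' @param units an `aq_units` tibble.
#' @param fine_res fine resolution (default 0.01).
#' @param n_per_day timesteps per day (default 8).
#' @return tibble `nuts_code`, `metric`, `year`, `value` over the seven
#'   daily-or-coarser metrics.
#' @export
reanalysis_unit_values <- function(rasters_by_pollutant, units,
                                   fine_res = 0.01, n_per_day = 8L) {
  daily <- lapply(rasters_by_pollutant, to_daily, n_per_day = n_per_day)
  mr <- cell_annual_metrics(daily)
  vectorize(mr, units, fine_res)
}
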