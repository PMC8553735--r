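#' Write and read the synthetic world's inputs as plain-text files
#'
#' Desk-scale counterparts of the production input formats: a station
#' metadata CSV, per-pollutant-year hourly CSVs (ISO-8601 UTC timestamp,
#' station id, value), a GeoJSON file of unit polygons with `nuts_code`
#' and `nuts_name` properties, and a long-format raster CSV with
#' `time, lat, lon, value` columns.
#'
#' @name aq_io
NULL

#' @rdname aq_io
#' @param stations station tibble.
#' @param path file path.
#' @export
write_stations_csv <- function(stations, path) {
  readr::write_csv(
    stations[, c("station_id", "lon", "lat", "type", "area_class")], path)
}

#' @rdname aq_io
#' @export
read_stations_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = "cddcc")
}

#' @rdname aq_io
#' @param series_list list of [hourly_series()] for one pollutant-year.
#' @export
write_hourly_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    t0 <- as.POSIXct(sprintf("%d-01-01", s$year), tz = "UTC")
    keep <- !is.na(s$values)
    tibble::tibble(
      timestamp = format(t0 + 3600 * (which(keep) - 1L),
                         "%Y-%m-%dT%H:%M:%SZ"),
      station_id = s$station_id,
      pollutant = s$pollutant,
      value = s$values[keep]
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
}

#' @rdname aq_io
#' @param year calendar year of the file's series.
#' @return `read_hourly_csv`: named list of [hourly_series()] keyed
#'   `station_id.pollutant`.
#' @export
read_hourly_csv <- function(path, year) {
  df <- readr::read_csv(path, show_col_types = FALSE, col_types = "cccd")
  t0 <- as.POSIXct(sprintf("%d-01-01", year), tz = "UTC")
  idx <- as.integer(round(as.numeric(
    difftime(as.POSIXct(df$timestamp, tz = "UTC",
                        format = "%Y-%m-%dT%H:%M:%SZ"),
             t0, units = "hours")))) + 1L
  out <- list()
  for (key in unique(paste(df$station_id, df$pollutant, sep = "."))) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sel <- df$station_id == parts[1] & df$pollutant == parts[2]
    v <- rep(NA_real_, hours_in_year(year))
    v[idx[sel]] <- df$value[sel]
    out[[key]] <- hourly_series(v, parts[2], year, parts[1])
  }
  out
}

#' @rdname aq_io
#' @param units an `aq_units` tibble.
#' @export
write_units_geojson <- function(units, path) {
  features <- lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    ring <- list(
      c(u$lon_min, u$lat_min), c(u$lon_max, u$lat_min),
      c(u$lon_max, u$lat_max), c(u$lon_min, u$lat_max),
      c(u$lon_min, u$lat_min)
    )
    list(
      type = "Feature",
      properties = list(nuts_code = u$nuts_code, nuts_name = u$nuts_name,
                        region = u$region),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
}

#' @rdname aq_io
#' @return `read_units_geojson`: an `aq_units` tibble (rectangular extents
#'   recovered from the polygon rings).
#' @export
read_units_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    lons <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    lats <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    tibble::tibble(
      nuts_code = f$properties$nuts_code,
      nuts_name = f$properties$nuts_name,
      region = f$properties$region,
      lon_min = min(lons), lon_max = max(lons),
      lat_min = min(lats), lat_max = max(lats)
    )
  })
  units <- dplyr::bind_rows(rows)
  attr(units, "domain") <- c(lon_min = min(units$lon_min),
                             lon_max = max(units$lon_max),
                             lat_min = min(units$lat_min),
                             lat_max = max(units$lat_max))
  class(units) <- c("aq_units", class(units))
  units
}

#' @rdname aq_io
#' @param raster an `aq_raster`.
#' @export
write_raster_csv <- function(raster, path) {
  grid <- expand.grid(lon = raster$lon, lat = raster$lat,
                      time = raster$times)
  readr::write_csv(tibble::tibble(
    time = grid$time, lat = grid$lat, lon = grid$lon,
    value = as.vector(raster$values)
  ), path)
}

#' @rdname aq_io
#' @param pollutant,res metadata to restore on the raster.
#' @return `read_raster_csv`: an `aq_raster`.
#' @export
read_raster_csv <- function(path, pollutant, year, res = 0.75) {
  df <- readr::read_csv(path, show_col_types = FALSE, col_types = "dddd")
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  times <- sort(unique(df$time))
  df <- df[order(df$time, df$lat, df$lon), ]
  structure(
    list(lon = lon, lat = lat, res = res, times = times,
         values = array(df$value,
                        dim = c(length(lon), length(lat), length(times))),
         pollutant = pollutant, year = as.integer(year)),
    class = "aq_raster"
  )
}

#' Write a synthetic world's inputs to a directory
#'
#' Stations CSV, units GeoJSON, per pollutant-year hourly CSVs and raster
#' CSVs. Mainly for inspection and for exercising the file-based entry
#' points; the in-memory pipeline does not round-trip through files.
#'
#' @param world an `aq_world`.
#' @param dir output directory.
#' @param years subset of years to write (default: all).
#' @param write_hourly,write_rasters toggles for the bulky parts.
#' @return invisibly, `dir`.
#' @export
write_world <- function(world, dir, years = world$config$years,
                        write_hourly = TRUE, write_rasters = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stations_csv(world$stations, file.path(dir, "stations.csv"))
  write_units_geojson(world$units, file.path(dir, "units.geojson"))
  readr::write_csv(world$measurements, file.path(dir, "measurements.csv"))
  readr::write_csv(world$ratification, file.path(dir, "ratification.csv"))
  for (y in years) {
    if (write_hourly) {
      for (p in AQ_POLLUTANTS) {
        sids <- world$measurements$station_id[
          world$measurements$pollutant == p]
        series <- Filter(Negate(is.null),
                         lapply(sids, world_series, world = world,
                                pollutant = p, year = y))
        if (length(series)) {
          write_hourly_csv(series, file.path(
            dir, sprintf("hourly_%s_%d.csv", gsub("\\.", "", p), y)))
        }
      }
    }
    if (write_rasters) {
      for (p in AQ_POLLUTANTS) {
        write_raster_csv(world$rasters[[p]][[as.character(y)]], file.path(
          dir, sprintf("raster_%s_%d.csv", gsub("\\.", "", p), y)))
      }
    }
  }
  invisible(dir)
}
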