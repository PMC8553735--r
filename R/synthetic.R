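#' Default study domain (Germany-like bounding box, degrees WGS84)
#' @return named numeric vector `lon_min, lon_max, lat_min, lat_max`.
#' @export
aq_default_domain <- function() {
  c(lon_min = 6, lon_max = 15, lat_min = 47.25, lat_max = 55.05)
}

#' Tile a domain into rectangular administrative units
#'
#' Partitions a bounding box into `n_units` non-overlapping rectangles whose
#' union is exactly the box. Rows are equal-height latitude bands; when
#' `n_units` is not a product of two integers close to a square, some rows
#' carry one extra column (ragged rows), so any positive count works. Codes
#' follow a `"DE"` + zero-padded index pattern and a synthetic NUTS-2-like
#' region code groups neighbouring rows.
#'
#' @param n_units positive integer number of units (default 402).
#' @param domain bounding box as in [aq_default_domain()].
#' @param n_regions number of region groups for the regional-average
#'   baseline (default 16, clipped to the number of rows).
#' @return tibble of class `aq_units` with columns `nuts_code`, `nuts_name`,
#'   `region`, `lon_min`, `lon_max`, `lat_min`, `lat_max`, `row`, `col`;
#'   the domain is kept as the `"domain"` attribute.
#' @export
generate_units <- function(n_units = 402L, domain = aq_default_domain(),
                           n_regions = 16L) {
  n_units <- as.integer(n_units)
  stopifnot(n_units >= 1L)
  if (domain[["lon_max"]] <= domain[["lon_min"]] ||
      domain[["lat_max"]] <= domain[["lat_min"]]) {
    stop("degenerate domain", call. = FALSE)
  }
  n_rows <- max(1L, as.integer(round(sqrt(n_units))))
  if (n_rows > n_units) n_rows <- n_units
  base_cols <- n_units %/% n_rows
  extra <- n_units %% n_rows            # this many rows get one extra column
  cols_per_row <- rep(base_cols, n_rows) + c(rep(1L, extra),
                                             rep(0L, n_rows - extra))

  lat_edges <- seq(domain[["lat_min"]], domain[["lat_max"]],
                   length.out = n_rows + 1L)
  rows <- lapply(seq_len(n_rows), function(r) {
    nc <- cols_per_row[r]
    lon_edges <- seq(domain[["lon_min"]], domain[["lon_max"]],
                     length.out = nc + 1L)
    tibble::tibble(
      row = r, col = seq_len(nc),
      lon_min = lon_edges[-(nc + 1L)], lon_max = lon_edges[-1L],
      lat_min = lat_edges[r], lat_max = lat_edges[r + 1L]
    )
  })
  units <- dplyr::bind_rows(rows)
  width <- max(3L, nchar(as.character(n_units)))
  units$nuts_code <- sprintf(paste0("DE%0", width, "d"), seq_len(n_units))
  units$nuts_name <- paste("Kreis", units$nuts_code)
  n_regions <- max(1L, min(as.integer(n_regions), n_rows))
  units$region <- sprintf("DER%02d",
                          ceiling(units$row * n_regions / n_rows))
  units <- units[, c("nuts_code", "nuts_name", "region",
                     "lon_min", "lon_max", "lat_min", "lat_max",
                     "row", "col")]
  attr(units, "domain") <- domain
  class(units) <- c("aq_units", class(units))
  units
}

#' Unit centroids
#' @param units an `aq_units` tibble.
#' @return tibble `nuts_code`, `lon`, `lat`.
#' @export
unit_centroids <- function(units) {
  tibble::tibble(
    nuts_code = units$nuts_code,
    lon = (units$lon_min + units$lon_max) / 2,
    lat = (units$lat_min + units$lat_max) / 2
  )
}

#' Default monitoring coverage per pollutant
#'
#' Fraction of units holding at least one background station of each
#' pollutant. Defaults reflect the sparse coverage of the German network,
#' where at most about half of the 402 counties are monitored for any
#' pollutant and fine particulate matter is the sparsest.
#' @export
aq_default_coverage <- function() {
  c(NO2 = 197 / 402, NO = 194 / 402, O3 = 197 / 402,
    PM10 = 188 / 402, "PM2.5" = 110 / 402)
}

#' Default station area-class mix
#' @export
aq_default_class_mix <- function() {
  c(urban = 0.35, suburban = 0.20, "rural-nearcity" = 0.10,
    "rural-regional" = 0.12, rural = 0.17, "rural-remote" = 0.06)
}

#' Place a synthetic monitoring network
#'
#' For each pollutant a random subset of units (fraction `coverage`) is
#' monitored; every monitored unit receives one or more background stations
#' placed uniformly within it, which measure exactly the pollutants their
#' unit was selected for. A fraction of monitored units additionally
#' receives a traffic or industrial station (which downstream filtering must
#' reject). Area classes are drawn from `class_mix`.
#'
#' @param units an `aq_units` tibble.
#' @param coverage named fraction in (0, 1] per pollutant
#'   (default [aq_default_coverage()]).
#' @param class_mix named probabilities over `AQ_AREA_CLASSES`.
#' @param extra_station_prob probability a monitored unit gets a second
#'   background station (default 0.3).
#' @param nonbackground_prob probability a monitored unit also gets one
#'   traffic/industrial station (default 0.25).
#' @param seed integer seed.
#' @return tibble with columns `station_id`, `nuts_code`, `lon`, `lat`,
#'   `type` (background/traffic/industrial), `area_class`, and a
#'   `measurements` attribute: tibble `station_id`, `pollutant`.
#' @export
generate_stations <- function(units, coverage = aq_default_coverage(),
                              class_mix = aq_default_class_mix(),
                              extra_station_prob = 0.3,
                              nonbackground_prob = 0.25,
                              seed = 1L) {
  if (nrow(units) == 0L) stop("no units", call. = FALSE)
  stopifnot(all(coverage > 0), all(coverage <= 1))
  set.seed(seed)
  n <- nrow(units)

  monitored <- lapply(coverage, function(f) {
    sort(sample.int(n, round(f * n)))
  })
  any_mon <- sort(unique(unlist(monitored)))

  station_rows <- list()
  meas_rows <- list()
  sid <- 0L
  for (i in any_mon) {
    pols <- names(monitored)[vapply(monitored, function(ix) i %in% ix,
                                    logical(1))]
    n_bg <- 1L + stats::rbinom(1L, 1L, extra_station_prob)
    n_extra <- stats::rbinom(1L, 1L, nonbackground_prob)
    types <- c(rep("background", n_bg),
               sample(c("traffic", "industrial"), n_extra, replace = TRUE))
    for (type in types) {
      sid <- sid + 1L
      id <- sprintf("ST%05d", sid)
      station_rows[[sid]] <- tibble::tibble(
        station_id = id,
        nuts_code = units$nuts_code[i],
        lon = stats::runif(1, units$lon_min[i], units$lon_max[i]),
        lat = stats::runif(1, units$lat_min[i], units$lat_max[i]),
        type = type,
        area_class = sample(names(class_mix), 1L, prob = class_mix)
      )
      meas_rows[[sid]] <- tibble::tibble(station_id = id, pollutant = pols)
    }
  }
  stations <- dplyr::bind_rows(station_rows)
  attr(stations, "measurements") <- dplyr::bind_rows(meas_rows)
  stations
}

#' Multiplicative station-class factor
#'
#' Urban sites see elevated NO2/NO/PM and depressed O3 relative to the unit
#' truth; remote sites the opposite. This is what makes the three averaging
#' scenarios differ measurably in synthetic worlds.
#'
#' @param area_class one of `AQ_AREA_CLASSES`.
#' @param pollutant one of `AQ_POLLUTANTS`.
#' @param delta urban increment magnitude (default 0.3; 0 disables).
#' @return positive scalar multiplier.
#' @export
class_factor <- function(area_class, pollutant, delta = 0.3) {
  lev <- c(urban = 1, suburban = 0.5, "rural-nearcity" = 0.25,
           "rural-regional" = -0.25, rural = -0.5, "rural-remote" = -0.6)
  s <- if (pollutant == "O3") -1 else 1
  1 + s * delta * lev[[area_class]]
}

# unit-mean-normalised seasonal x diurnal shape for one year
hourly_shape <- function(year, seasonal_amp, diurnal_amp,
                         seasonal_peak_doy, diurnal_peak_hour) {
  H <- hours_in_year(year)
  doy <- ((seq_len(H) - 1L) %/% 24L) + 1L
  hod <- (seq_len(H) - 1L) %% 24L
  s <- 1 + seasonal_amp * cos(2 * pi * (doy - seasonal_peak_doy) /
                                days_in_year(year))
  d <- 1 + diurnal_amp * cos(2 * pi * (hod - diurnal_peak_hour) / 24)
  f <- s * d
  f / mean(f)
}

# per-pollutant default shape parameters: winter-peaking NO2/NO/PM,
# summer-peaking O3; afternoon O3 peak, morning-rush peak otherwise
aq_shape_defaults <- function(pollutant) {
  switch(pollutant,
    O3 = list(seasonal_peak_doy = 200, diurnal_peak_hour = 15),
    list(seasonal_peak_doy = 15, diurnal_peak_hour = 8)
  )
}

#' Generate one synthetic hourly station series
#'
#' Hourly values are `truth_value` times a unit-annual-mean shape — the
#' product of seasonal and diurnal sinusoids and a lognormal day-to-day
#' "episode" factor emulating synoptic pollution episodes (which is what
#' makes daily exceedance thresholds attainable at realistic annual
#' means) — plus Gaussian noise, clipped at zero; a fraction of hours is
#' then set missing uniformly at random (or as one contiguous block, which
#' stresses the data-capture rule with structured gaps).
#'
#' With `noise_sd = 0`, `missing_fraction = 0` and zero amplitudes the
#' annual mean equals `truth_value` exactly.
#'
#' @param pollutant one of `AQ_POLLUTANTS`.
#' @param year calendar year.
#' @param truth_value non-negative annual-mean concentration (ug/m3).
#' @param noise_sd Gaussian noise standard deviation (ug/m3, default 3).
#' @param missing_fraction fraction of hours missing, in `[0, 1)`.
#' @param seasonal_amp,diurnal_amp relative amplitudes (defaults 0.25, 0.15).
#' @param episode_sd lognormal sd of the daily episode factor
#'   (default 0.4; 0 disables).
#' @param block_missing if `TRUE`, missingness is one contiguous block.
#' @param seed integer seed (optional).
#' @param station_id label carried on the series.
#' @return an [hourly_series()].
#' @export
generate_hourly_series <- function(pollutant, year, truth_value,
                                   noise_sd = 3, missing_fraction = 0.05,
                                   seasonal_amp = 0.25, diurnal_amp = 0.15,
                                   episode_sd = 0.4,
                                   block_missing = FALSE, seed = NULL,
                                   station_id = NA_character_) {
  if (truth_value < 0) stop("negative truth_value", call. = FALSE)
  stopifnot(missing_fraction >= 0, missing_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  sh <- aq_shape_defaults(pollutant)
  f <- hourly_shape(year, seasonal_amp, diurnal_amp,
                    sh$seasonal_peak_doy, sh$diurnal_peak_hour)
  if (episode_sd > 0) {
    ed <- exp(stats::rnorm(days_in_year(year), 0, episode_sd))
    f <- f * rep(ed, each = 24L)
    f <- f / mean(f)
  }
  H <- hours_in_year(year)
  v <- pmax(0, truth_value * f + stats::rnorm(H, 0, noise_sd))
  n_miss <- round(missing_fraction * H)
  if (n_miss > 0) {
    if (block_missing) {
      start <- sample.int(H - n_miss + 1L, 1L)
      v[start:(start + n_miss - 1L)] <- NA_real_
    } else {
      v[sample.int(H, n_miss)] <- NA_real_
    }
  }
  hourly_series(v, pollutant, year, station_id)
}

#' Regular lon/lat grid covering a domain
#'
#' Cell-center registered grid at resolution `res` (degrees), anchored at
#' the domain's lower-left corner and extended outward until the whole
#' domain is covered.
#'
#' @param domain bounding box.
#' @param res cell size in degrees (default 0.75).
#' @return list with `lon`, `lat` (cell-center vectors) and `res`.
#' @export
aq_grid <- function(domain = aq_default_domain(), res = 0.75) {
  nlon <- ceiling((domain[["lon_max"]] - domain[["lon_min"]]) / res - 1e-9)
  nlat <- ceiling((domain[["lat_max"]] - domain[["lat_min"]]) / res - 1e-9)
  list(
    lon = domain[["lon_min"]] + res * (seq_len(nlon) - 0.5),
    lat = domain[["lat_min"]] + res * (seq_len(nlat) - 0.5),
    res = res
  )
}

#' Area weights of units within coarse grid cells
#'
#' Approximates, by a regular subsample of points inside each cell, the area
#' fraction of every unit under every cell. Subsample points falling outside
#' the tiled domain (grid cells may overhang it) are clamped to the nearest
#' interior location, so each cell's weights sum to one.
#'
#' @param units an `aq_units` tibble.
#' @param grid coarse grid from [aq_grid()].
#' @param n_sub subsample points per cell side (default 15).
#' @return matrix `[n_cells, n_units]` (cells in lon-fastest order).
#' @export
cell_unit_weights <- function(units, grid, n_sub = 15L) {
  domain <- attr(units, "domain")
  half <- grid$res / 2
  off <- grid$res * ((seq_len(n_sub) - 0.5) / n_sub) - half
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  px <- as.vector(outer(off, grid$lon, `+`))   # n_sub x nlon, lon-major
  py <- as.vector(outer(off, grid$lat, `+`))
  px <- pmin(pmax(px, domain[["lon_min"]] + 1e-9), domain[["lon_max"]] - 1e-9)
  py <- pmin(pmax(py, domain[["lat_min"]] + 1e-9), domain[["lat_max"]] - 1e-9)
  cell_i <- rep(seq_len(nlon), each = n_sub)
  cell_j <- rep(seq_len(nlat), each = n_sub)
  pts_lon <- rep(px, times = length(py))
  pts_lat <- rep(py, each = length(px))
  idx_cell <- rep(cell_i, times = length(py)) +
    (rep(cell_j, each = length(px)) - 1L) * nlon
  unit_idx <- locate_points(pts_lon, pts_lat, units)
  ncell <- nlon * nlat
  tab <- tabulate((unit_idx - 1L) * ncell + idx_cell, ncell * nrow(units))
  matrix(tab, ncell, nrow(units)) / (n_sub^2)
}

#' Generate a synthetic 3-hourly reanalysis raster for one pollutant-year
#'
#' Each cell's base value is an affine function (`slope`, `intercept`) of
#' the area-interpolated unit truth under the cell, modulated in time by a
#' unit-annual-mean seasonal shape, plus Gaussian noise, clipped at zero.
#' With zero noise the cell's annual mean is exactly
#' `slope * truth + intercept`, which is the recovery target for the
#' scaling-function tests.
#'
#' @param units an `aq_units` tibble.
#' @param truth_by_unit numeric vector, one truth value per unit
#'   (ug/m3, unit order).
#' @param pollutant one of `AQ_POLLUTANTS`.
#' @param year calendar year.
#' @param link named list/vector with `slope`, `intercept`, `noise_sd`.
#' @param grid coarse grid from [aq_grid()]; must cover all units.
#' @param n_per_day timesteps per day (default 8, i.e. 3-hourly).
#' @param seasonal_amp relative seasonal amplitude of the raster field
#'   (default 0.15; 0 gives a time-constant field).
#' @param episode_sd lognormal sd of a spatially uniform daily episode
#'   factor (default 0.4; normalised to unit annual mean so the affine
#'   closure is preserved).
#' @param cell_weights optional precomputed [cell_unit_weights()] for this
#'   `units`/`grid` pair (recomputed when `NULL`).
#' @param seed integer seed.
#' @return object of class `aq_raster`: list with `lon`, `lat`, `res`,
#'   `times` (fractional day-of-year), `values` array
#'   `[lon, lat, time]`, `pollutant`, `year`.
#' @export
generate_rasters <- function(units, truth_by_unit, pollutant, year, link,
                             grid = aq_grid(attr(units, "domain")),
                             n_per_day = 8L, seasonal_amp = 0.15,
                             episode_sd = 0.4,
                             cell_weights = NULL, seed = 1L) {
  domain <- attr(units, "domain")
  half <- grid$res / 2
  if (min(grid$lon) - half > min(units$lon_min) + 1e-9 ||
      max(grid$lon) + half < max(units$lon_max) - 1e-9 ||
      min(grid$lat) - half > min(units$lat_min) + 1e-9 ||
      max(grid$lat) + half < max(units$lat_max) - 1e-9) {
    stop("domain mismatch: grid does not cover the units", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(cell_weights)) cell_weights <- cell_unit_weights(units, grid)
  base <- matrix(as.vector(cell_weights %*% truth_by_unit),
                 length(grid$lon), length(grid$lat))
  base <- link[["slope"]] * base + link[["intercept"]]

  nd <- days_in_year(year)
  nt <- nd * n_per_day
  sh <- aq_shape_defaults(pollutant)
  doy <- ((seq_len(nt) - 1L) %/% n_per_day) + 1L
  tf <- 1 + seasonal_amp * cos(2 * pi * (doy - sh$seasonal_peak_doy) / nd)
  if (episode_sd > 0) {
    ed <- exp(stats::rnorm(nd, 0, episode_sd))
    tf <- tf * rep(ed, each = n_per_day)
  }
  tf <- tf / mean(tf)

  nlon <- length(grid$lon); nlat <- length(grid$lat)
  vals <- array(base, dim = c(nlon, nlat, nt))
  vals <- sweep(vals, 3L, tf, `*`)
  if (link[["noise_sd"]] > 0) {
    vals <- vals + stats::rnorm(length(vals), 0, link[["noise_sd"]])
  }
  vals <- pmax(vals, 0)
  structure(
    list(lon = grid$lon, lat = grid$lat, res = grid$res,
         times = (seq_len(nt) - 0.5) / n_per_day,
         values = vals, pollutant = pollutant, year = as.integer(year)),
    class = "aq_raster"
  )
}

#' Default affine links between reanalysis field and unit truth
#' @return tibble `pollutant`, `slope`, `intercept`, `noise_sd`.
#' @export
aq_default_links <- function() {
  tibble::tribble(
    ~pollutant, ~slope, ~intercept, ~noise_sd,
    "NO2",   0.80, 3.0, 1.0,
    "NO",    0.70, 1.0, 0.8,
    "O3",    0.90, 4.0, 2.0,
    "PM10",  0.85, 2.0, 1.0,
    "PM2.5", 0.80, 1.5, 0.8
  )
}

#' Synthetic-world configuration
#'
#' Collects every tunable of the generator in one list. `noiseless = TRUE`
#' zeroes all noise sources, missingness, seasonal/diurnal amplitudes and
#' the station-class increment, giving the configuration under which the
#' full pipeline must reproduce the truth field exactly for monitored units.
#'
#' @param n_units number of units (default 402).
#' @param years integer vector of years (default 2010:2019).
#' @param domain bounding box.
#' @param coverage named per-pollutant monitored-unit fraction.
#' @param class_mix area-class probabilities.
#' @param links affine raster links (tibble as [aq_default_links()]).
#' @param base_level named per-pollutant typical annual mean (ug/m3).
#' @param spatial_gradient relative truth-field range across the domain
#'   (default 0.08 in each direction).
#' @param truth_noise_sd lognormal sd of per-unit truth scatter
#'   (default 0.06).
#' @param noise_sd hourly Gaussian noise sd (ug/m3, default 3).
#' @param missing_fraction hourly missingness (default 0.05).
#' @param seasonal_amp,diurnal_amp hourly shape amplitudes.
#' @param episode_sd lognormal sd of the daily episode factor (stations
#'   and rasters; default 0.4).
#' @param raster_seasonal_amp raster temporal amplitude.
#' @param class_delta urban increment magnitude (default 0.3).
#' @param ratified_prob probability a station-year is ratified
#'   (default 0.9).
#' @param tz_offset day-boundary offset in hours (default 0 = UTC).
#' @param coarse_res,fine_res raster resolutions in degrees
#'   (defaults 0.75 and 0.01).
#' @param noiseless if `TRUE`, override all stochastic/shape parameters
#'   to zero.
#' @param seed master seed.
#' @return a config list of class `aq_config`.
#' @export
aq_config <- function(n_units = 402L, years = 2010:2019,
                      domain = aq_default_domain(),
                      coverage = aq_default_coverage(),
                      class_mix = aq_default_class_mix(),
                      links = aq_default_links(),
                      base_level = c(NO2 = 18, NO = 10, O3 = 48,
                                     PM10 = 19, "PM2.5" = 12),
                      spatial_gradient = 0.08,
                      truth_noise_sd = 0.06,
                      noise_sd = 3, missing_fraction = 0.05,
                      seasonal_amp = 0.25, diurnal_amp = 0.15,
                      episode_sd = 0.4,
                      raster_seasonal_amp = 0.15,
                      class_delta = 0.3, ratified_prob = 0.9,
                      tz_offset = 0L,
                      coarse_res = 0.75, fine_res = 0.01,
                      noiseless = FALSE, seed = 1L) {
  cfg <- list(
    n_units = as.integer(n_units), years = as.integer(years),
    domain = domain, coverage = coverage, class_mix = class_mix,
    links = links, base_level = base_level,
    spatial_gradient = spatial_gradient, truth_noise_sd = truth_noise_sd,
    noise_sd = noise_sd, missing_fraction = missing_fraction,
    seasonal_amp = seasonal_amp, diurnal_amp = diurnal_amp,
    episode_sd = episode_sd,
    raster_seasonal_amp = raster_seasonal_amp,
    class_delta = class_delta, ratified_prob = ratified_prob,
    tz_offset = as.integer(tz_offset),
    coarse_res = coarse_res, fine_res = fine_res,
    seed = as.integer(seed)
  )
  if (noiseless) {
    cfg$truth_noise_sd <- 0
    cfg$noise_sd <- 0
    cfg$missing_fraction <- 0
    cfg$seasonal_amp <- 0
    cfg$diurnal_amp <- 0
    cfg$episode_sd <- 0
    cfg$raster_seasonal_amp <- 0
    cfg$class_delta <- 0
    cfg$links$noise_sd <- 0
  }
  structure(cfg, class = "aq_config")
}

# deterministic per-key seed below 2^31, independent of generation order
key_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) else
      as.integer(x)
  }))
  s <- as.double(seed)
  for (p in parts) s <- (s * 1103515245 + as.double(p) + 12345) %% 2147483647
  as.integer(s)
}

#' Generate a complete synthetic world
#'
#' Builds units, the per-unit/pollutant/year truth field (a smooth spatial
#' gradient around a pollutant base level with optional per-unit lognormal
#' scatter and a mild downward year trend for NO2/PM), the station network
#' with per-station-year ratification flags, and one 3-hourly raster per
#' pollutant-year affinely linked to the truth field. Hourly station series
#' are not materialised here (a decade of them would be large); they are
#' produced on demand by [world_series()] with per-key deterministic seeds,
#' so regeneration is reproducible regardless of the order of access.
#'
#' @param config an [aq_config()].
#' @return list of class `aq_world`: `units`, `truth` (tibble `nuts_code`,
#'   `pollutant`, `year`, `truth`), `stations`, `measurements`,
#'   `ratification`, `rasters` (nested list `[[pollutant]][[as.character(year)]]`),
#'   `links`, `config`.
#' @export
generate_world <- function(config = aq_config()) {
  stopifnot(inherits(config, "aq_config"))
  units <- generate_units(config$n_units, config$domain)
  cen <- unit_centroids(units)
  domain <- config$domain
  gx <- (cen$lon - mean(range(cen$lon))) /
    (domain[["lon_max"]] - domain[["lon_min"]])
  gy <- (cen$lat - mean(range(cen$lat))) /
    (domain[["lat_max"]] - domain[["lat_min"]])

  set.seed(key_seed(config$seed, 101L))
  truth_rows <- list()
  for (p in AQ_POLLUTANTS) {
    base <- config$base_level[[p]]
    # fixed per-pollutant orientation of the spatial gradient
    ori <- match(p, AQ_POLLUTANTS)
    sx <- c(1, -1, 1, -1, 1)[ori]
    sy <- c(1, 1, -1, -1, 1)[ori]
    spatial <- 1 + config$spatial_gradient * (sx * gx + sy * gy)
    scatter <- if (config$truth_noise_sd > 0) {
      exp(stats::rnorm(nrow(units), 0, config$truth_noise_sd))
    } else rep(1, nrow(units))
    for (y in config$years) {
      trend <- if (p %in% c("NO2", "NO", "PM10", "PM2.5")) {
        1 - 0.01 * (y - config$years[1])
      } else 1
      truth_rows[[paste(p, y)]] <- tibble::tibble(
        nuts_code = units$nuts_code, pollutant = p, year = as.integer(y),
        truth = base * spatial * scatter * trend
      )
    }
  }
  truth <- dplyr::bind_rows(truth_rows)

  stations <- generate_stations(
    units, config$coverage, config$class_mix,
    seed = key_seed(config$seed, 202L)
  )
  measurements <- attr(stations, "measurements")

  set.seed(key_seed(config$seed, 303L))
  ratification <- tidyr::expand_grid(
    station_id = stations$station_id, year = config$years
  )
  ratification$ratified <-
    stats::runif(nrow(ratification)) < config$ratified_prob

  grid <- aq_grid(domain, config$coarse_res)
  weights <- cell_unit_weights(units, grid)
  links <- config$links
  rasters <- list()
  for (p in AQ_POLLUTANTS) {
    lk <- links[links$pollutant == p, ]
    rasters[[p]] <- list()
    for (y in config$years) {
      tr <- truth$truth[truth$pollutant == p & truth$year == y]
      rasters[[p]][[as.character(y)]] <- generate_rasters(
        units, tr, p, y,
        link = list(slope = lk$slope, intercept = lk$intercept,
                    noise_sd = lk$noise_sd),
        grid = grid, seasonal_amp = config$raster_seasonal_amp,
        episode_sd = config$episode_sd,
        cell_weights = weights,
        seed = key_seed(config$seed, 404L, p, y)
      )
    }
  }

  structure(
    list(units = units, truth = truth, stations = stations,
         measurements = measurements, ratification = ratification,
         rasters = rasters, links = links, config = config),
    class = "aq_world"
  )
}

#' Hourly series of one station-pollutant-year of a synthetic world
#'
#' Deterministic in (world seed, station, pollutant, year); returns `NULL`
#' when the station does not measure the pollutant. The sampled truth is the
#' unit truth times the station's class factor.
#'
#' @param world an `aq_world`.
#' @param station_id,pollutant,year key.
#' @return an [hourly_series()] or `NULL`.
#' @export
world_series <- function(world, station_id, pollutant, year) {
  meas <- world$measurements
  if (!any(meas$station_id == station_id & meas$pollutant == pollutant)) {
    return(NULL)
  }
  st <- world$stations[world$stations$station_id == station_id, ]
  tr <- world$truth
  tv <- tr$truth[tr$nuts_code == st$nuts_code & tr$pollutant == pollutant &
                   tr$year == year]
  cfg <- world$config
  generate_hourly_series(
    pollutant, year,
    truth_value = tv * class_factor(st$area_class, pollutant,
                                    cfg$class_delta),
    noise_sd = cfg$noise_sd, missing_fraction = cfg$missing_fraction,
    seasonal_amp = cfg$seasonal_amp, diurnal_amp = cfg$diurnal_amp,
    episode_sd = cfg$episode_sd,
    seed = key_seed(cfg$seed, 505L, station_id, pollutant, year),
    station_id = station_id
  )
}
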