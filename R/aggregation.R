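#' Locate points within units
#'
#' Returns for each point the index (in `units` row order, which is code
#' order) of the containing rectangle. Points on a shared edge resolve to
#' the first unit in code order — a documented deterministic tie-break.
#'
#' @param lon,lat numeric vectors.
#' @param units an `aq_units` tibble.
#' @return integer vector of unit row indices.
#' @export
locate_points <- function(lon, lat, units) {
  n <- length(lon)
  res <- rep(NA_integer_, n)
  for (i in seq_len(nrow(units))) {
    sel <- is.na(res) &
      lon >= units$lon_min[i] & lon <= units$lon_max[i] &
      lat >= units$lat_min[i] & lat <= units$lat_max[i]
    res[sel] <- i
  }
  if (anyNA(res)) {
    stop("station outside domain: ", sum(is.na(res)), " point(s) in no unit",
         call. = FALSE)
  }
  res
}

#' Geo-locate stations into units
#'
#' @param stations tibble with `lon`, `lat`.
#' @param units an `aq_units` tibble.
#' @return character vector of unit codes, one per station.
#' @export
locate_station <- function(stations, units) {
  units$nuts_code[locate_points(stations$lon, stations$lat, units)]
}

#' Scenario specification
#'
#' The three unit-level averaging strategies over background stations:
#' `"average"` uses all stations; `"urban"` and `"remote"` use only the
#' stations of the most preferred area class present (strict fallback down
#' the preference order). `rural-remote` sits at the remote end: last
#' under `"urban"`, first under `"remote"`.
#'
#' @param name `"average"`, `"urban"` or `"remote"`.
#' @return list with `name` and `preference` (character vector, empty for
#'   `"average"`).
#' @export
scenario_spec <- function(name = c("average", "urban", "remote")) {
  name <- match.arg(name)
  preference <- switch(name,
    average = character(0),
    urban = c("urban", "suburban", "rural-nearcity", "rural-regional",
              "rural", "rural-remote"),
    remote = c("rural-remote", "rural", "rural-regional", "rural-nearcity",
               "suburban", "urban")
  )
  list(name = name, preference = preference)
}

#' All three scenario names
#' @export
AQ_SCENARIOS <- c("average", "urban", "remote")

#' Select the stations contributing to one unit-metric value
#'
#' Selection is per metric: a station lacking one pollutant can still anchor
#' another. For the preference scenarios, only the first area class in the
#' preference order with at least one non-missing value is used; later
#' classes serve as fallback when earlier ones have none.
#'
#' @param area_class character vector of station classes.
#' @param value numeric metric values (`NA` = unavailable).
#' @param scenario a [scenario_spec()] or scenario name.
#' @return logical selection vector (possibly all `FALSE`).
#' @export
select_stations <- function(area_class, value, scenario) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  has <- !is.na(value)
  if (!any(has)) return(rep(FALSE, length(value)))
  if (!length(scenario$preference)) return(has)
  rank <- match(area_class, scenario$preference)
  best <- min(rank[has], na.rm = TRUE)
  has & !is.na(rank) & rank == best
}

#' Aggregate station metrics to units under one scenario
#'
#' Joins station metrics with their unit, filters to background stations,
#' applies per-metric scenario selection and takes the unweighted arithmetic
#' mean of the selected values. Exceedance-count means are kept as reals
#' here; rounding to integers happens only when the final files are
#' written. Also records which area classes contributed and whether every
#' contributing station-year was ratified.
#'
#' @param station_metrics tibble from [station_metrics_table()].
#' @param stations station tibble (`station_id`, `type`, `area_class`,
#'   `lon`, `lat`).
#' @param units an `aq_units` tibble.
#' @param scenario scenario name or [scenario_spec()].
#' @param ratification optional tibble `station_id`, `year`, `ratified`.
#' @return long tibble `nuts_code`, `year`, `scenario`, `metric`, `value`,
#'   `n_stations`, `station_types`, `ratified`; units with no qualifying
#'   station have `NA` value (flagged for gap filling).
#' @export
aggregate_units <- function(station_metrics, stations, units, scenario,
                            ratification = NULL) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  bg <- stations[tolower(stations$type) == "background", ]
  bg$nuts_code <- locate_station(bg, units)
  df <- dplyr::inner_join(station_metrics,
                          bg[, c("station_id", "nuts_code", "area_class")],
                          by = "station_id")
  if (!is.null(ratification)) {
    df <- dplyr::left_join(df, ratification, by = c("station_id", "year"))
  } else {
    df$ratified <- TRUE
  }
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(AQ_METRICS),
                              names_to = "metric", values_to = "value")
  agg <- long |>
    dplyr::group_by(.data$nuts_code, .data$year, .data$metric) |>
    dplyr::summarise(
      value = {
        sel <- select_stations(.data$area_class, .data$value, scenario)
        if (any(sel)) mean(.data$value[sel]) else NA_real_
      },
      n_stations = sum(select_stations(.data$area_class, .data$value,
                                       scenario)),
      station_types = {
        sel <- select_stations(.data$area_class, .data$value, scenario)
        paste(sort(unique(.data$area_class[sel])), collapse = ";")
      },
      ratified = {
        sel <- select_stations(.data$area_class, .data$value, scenario)
        if (any(sel)) all(.data$ratified[sel]) else NA
      },
      .groups = "drop"
    )
  # complete to every unit x year x metric so gap filling sees the holes
  full <- tidyr::expand_grid(
    nuts_code = units$nuts_code,
    year = sort(unique(station_metrics$year)),
    metric = AQ_METRICS
  )
  out <- dplyr::left_join(full, agg,
                          by = c("nuts_code", "year", "metric"))
  out$n_stations[is.na(out$n_stations)] <- 0L
  out$station_types[is.na(out$station_types)] <- ""
  out$scenario <- scenario$name
  out[, c("nuts_code", "year", "scenario", "metric", "value",
          "n_stations", "station_types", "ratified")]
}

#' Quantiles of relative differences between scenarios
#'
#' For each metric and each non-reference scenario, the distribution of
#' `|scenario - average| / average` over unit-years where both values are
#' present and the average-scenario value is positive; reports the 95th
#' percentile (linear-interpolation quantile) as a fraction. Unit-years
#' with a zero average value are excluded and counted.
#'
#' @param unit_table long tibble as rows of [aggregate_units()] stacked
#'   over all three scenarios.
#' @param probs quantile levels (default 0.95).
#' @return tibble `metric`, `scenario`, `prob`, `quantile`, `n`, `n_zero`.
#' @export
compare_scenarios <- function(unit_table, probs = 0.95) {
  stopifnot(all(AQ_SCENARIOS %in% unit_table$scenario))
  wide <- tidyr::pivot_wider(
    unit_table[, c("nuts_code", "year", "scenario", "metric", "value")],
    names_from = "scenario", values_from = "value"
  )
  out <- list()
  for (m in unique(wide$metric)) {
    w <- wide[wide$metric == m, ]
    for (sc in setdiff(AQ_SCENARIOS, "average")) {
      both <- !is.na(w$average) & !is.na(w[[sc]])
      zero <- both & w$average == 0
      use <- both & w$average > 0
      rel <- abs(w[[sc]][use] - w$average[use]) / w$average[use]
      out[[paste(m, sc)]] <- tibble::tibble(
        metric = m, scenario = sc, prob = probs,
        quantile = if (length(rel)) {
          as.numeric(stats::quantile(rel, probs, type = 7))
        } else NA_real_,
        n = sum(use), n_zero = sum(zero)
      )
    }
  }
  dplyr::bind_rows(out)
}
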