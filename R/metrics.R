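#' Hourly concentration series
#'
#' Container for one station-pollutant-year vector of hourly concentrations
#' in ug/m3. Hour 1 is 00:00-01:00 UTC on January 1; missing hours are `NA`.
#' Length must match the calendar (8760 hours, 8784 in leap years).
#'
#' @param values numeric vector of hourly concentrations with `NA` for
#'   missing hours; non-missing values must be non-negative.
#' @param pollutant one of `AQ_POLLUTANTS`.
#' @param year integer calendar year.
#' @param station_id station identifier (optional label).
#' @return an object of class `aq_hourly`.
#' @export
hourly_series <- function(values, pollutant, year, station_id = NA_character_) {
  pollutant <- match.arg(pollutant, AQ_POLLUTANTS)
  year <- as.integer(year)
  if (length(values) != hours_in_year(year)) {
    stop("calendar mismatch: series has ", length(values), " hours, year ",
         year, " has ", hours_in_year(year), call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("negative concentrations in hourly series", call. = FALSE)
  }
  structure(
    list(station_id = station_id, pollutant = pollutant, year = year,
         values = as.numeric(values)),
    class = "aq_hourly"
  )
}

#' @export
print.aq_hourly <- function(x, ...) {
  cat(sprintf("<aq_hourly> %s %s %d: %d hours, %.1f%% coverage\n",
              x$station_id, x$pollutant, x$year, length(x$values),
              100 * coverage(x)))
  invisible(x)
}

#' Annual data capture of an hourly series
#'
#' Fraction of the year's hours with a non-missing value. Station-years with
#' capture below the `min_coverage` threshold (default 0.8) are excluded
#' from every annual metric, so incomplete series cannot introduce a
#' seasonal bias.
#'
#' @param series an [hourly_series()].
#' @return fraction in `[0, 1]`.
#' @export
coverage <- function(series) {
  stopifnot(inherits(series, "aq_hourly"))
  mean(!is.na(series$values))
}

#' Annual mean concentration
#'
#' Mean over non-missing hours, or `NA` when annual data capture is below
#' `min_coverage`.
#'
#' @inheritParams coverage
#' @param min_coverage minimum fraction of hours required (default 0.8).
#' @return annual mean in ug/m3, or `NA`.
#' @export
annual_mean <- function(series, min_coverage = 0.8) {
  if (coverage(series) < min_coverage) return(NA_real_)
  mean(series$values, na.rm = TRUE)
}

#' Count of hourly exceedances
#'
#' Number of non-missing hours strictly above `threshold`, or `NA` when the
#' series fails the data-capture rule. Used with threshold 200 ug/m3 for NO2.
#'
#' @inheritParams annual_mean
#' @param threshold concentration threshold in ug/m3 (> 0); exceedance is
#'   strict (`value > threshold`).
#' @return integer count or `NA`.
#' @export
count_hourly_exceedances <- function(series, threshold, min_coverage = 0.8) {
  stopifnot(threshold > 0)
  if (coverage(series) < min_coverage) return(NA_integer_)
  as.integer(sum(series$values > threshold, na.rm = TRUE))
}

# align an hourly vector to local-day boundaries: returns a vector whose
# position (d-1)*24 + h is local hour h of day d, padded with NA where the
# local day extends outside the year
align_to_days <- function(values, year, tz_offset = 0) {
  nd <- days_in_year(year)
  out <- rep(NA_real_, nd * 24L)
  u <- seq_along(values) - 1L              # UTC hour index, 0-based
  l <- u + tz_offset                       # local hour index, 0-based
  keep <- l >= 0L & l < nd * 24L
  out[l[keep] + 1L] <- values[keep]
  out
}

#' Daily statistic of an hourly series
#'
#' Per calendar day, the mean or maximum over the day's non-missing hours. A
#' day is valid only when at least `min_hours` of its 24 hourly values are
#' present (default 18, i.e. 75 percent); invalid days are `NA`. Day
#' boundaries are taken in UTC by default; `tz_offset` shifts them (hours
#' east of UTC).
#'
#' @inheritParams coverage
#' @param statistic `"mean"` or `"max"`.
#' @param min_hours minimum valid hours for a valid day (default 18).
#' @param tz_offset integer hour offset applied to day boundaries (default 0).
#' @return numeric vector of length 365/366 with `NA` for invalid days.
#' @export
daily_aggregate <- function(series, statistic = c("mean", "max"),
                            min_hours = 18L, tz_offset = 0L) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(series, "aq_hourly"))
  nd <- days_in_year(series$year)
  m <- matrix(align_to_days(series$values, series$year, tz_offset),
              nrow = 24L, ncol = nd)
  nvalid <- colSums(!is.na(m))
  out <- if (statistic == "mean") {
    colMeans(m, na.rm = TRUE)
  } else {
    suppressWarnings(apply(m, 2L, max, na.rm = TRUE))
  }
  out[nvalid < min_hours] <- NA_real_
  out[!is.finite(out)] <- NA_real_
  out
}

#' Count of daily exceedances
#'
#' Number of non-missing days of a daily vector strictly above `threshold`.
#' Used with 50 ug/m3 for the PM10 daily mean and 120 ug/m3 for the O3 daily
#' mean. Eligibility of the parent series (the annual 80 percent rule) is
#' enforced by the caller, which passes `NA` days through untouched.
#'
#' @param daily numeric daily vector as returned by [daily_aggregate()].
#' @param threshold daily-mean threshold in ug/m3 (> 0); strict exceedance.
#' @return integer count.
#' @export
count_daily_exceedances <- function(daily, threshold) {
  stopifnot(threshold > 0)
  as.integer(sum(daily > threshold, na.rm = TRUE))
}

#' Daily maximum running 8-hour mean
#'
#' For each day, the maximum over the 24 running 8-hour means whose window
#' ends in that day (window-end attribution). An 8-hour mean is valid when
#' at least `min_hours_window` of its 8 hours are present (default 6); a day
#' is valid when at least `min_windows_day` of its 24 windows are valid
#' (default 18). Windows reaching before the start of the year see missing
#' hours there.
#'
#' @inheritParams daily_aggregate
#' @param min_hours_window minimum present hours for a valid window
#'   (default 6 of 8).
#' @param min_windows_day minimum valid windows for a valid day
#'   (default 18 of 24).
#' @return numeric vector of length 365/366; annual statistic is
#'   `max(..., na.rm = TRUE)` over it.
#' @export
max_8h_daily <- function(series, min_hours_window = 6L, min_windows_day = 18L,
                         tz_offset = 0L) {
  stopifnot(inherits(series, "aq_hourly"))
  nd <- days_in_year(series$year)
  w <- align_to_days(series$values, series$year, tz_offset)
  n <- length(w)
  v0 <- ifelse(is.na(w), 0, w)
  cs <- c(0, cumsum(v0))
  cn <- c(0, cumsum(!is.na(w)))
  j <- seq_len(n)
  lo <- pmax(j - 8L, 0L)
  wsum <- cs[j + 1L] - cs[lo + 1L]
  wcnt <- cn[j + 1L] - cn[lo + 1L]
  mean8 <- ifelse(wcnt >= min_hours_window, wsum / wcnt, NA_real_)
  m <- matrix(mean8, nrow = 24L, ncol = nd)
  nvalid <- colSums(!is.na(m))
  out <- suppressWarnings(apply(m, 2L, max, na.rm = TRUE))
  out[nvalid < min_windows_day] <- NA_real_
  out[!is.finite(out)] <- NA_real_
  out
}

#' Assemble the eleven annual metrics for one station-year
#'
#' Computes every metric available from the supplied per-pollutant hourly
#' series. A pollutant's metrics are `NA` when its series is absent or fails
#' the annual data-capture rule. Only background stations are eligible for
#' unit aggregation; traffic and industrial stations are filtered out before
#' this function is reached.
#'
#' @param series_by_pollutant named list of [hourly_series()], names in
#'   `AQ_POLLUTANTS`.
#' @param year calendar year (must match every series).
#' @param min_coverage annual data-capture threshold (default 0.8).
#' @param tz_offset hour offset for day boundaries (default 0 = UTC).
#' @param min_hours_day,min_hours_window,min_windows_day daily and 8-hour
#'   window validity rules (defaults 18/24, 6/8, 18/24).
#' @return one-row tibble on the `AQ_METRICS` schema.
#' @export
station_metric_vector <- function(series_by_pollutant, year,
                                  min_coverage = 0.8, tz_offset = 0L,
                                  min_hours_day = 18L, min_hours_window = 6L,
                                  min_windows_day = 18L) {
  bad <- setdiff(names(series_by_pollutant), AQ_POLLUTANTS)
  if (length(bad)) {
    stop("unknown pollutant label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mv <- stats::setNames(rep(NA_real_, length(AQ_METRICS)), AQ_METRICS)

  eligible <- function(p) {
    s <- series_by_pollutant[[p]]
    !is.null(s) && s$year == year && coverage(s) >= min_coverage
  }

  if (eligible("NO2")) {
    s <- series_by_pollutant[["NO2"]]
    mv["no2_avg"] <- annual_mean(s, min_coverage)
    mv["no2_hours_gt_200"] <-
      count_hourly_exceedances(s, AQ_THRESHOLDS[["NO2_hourly"]], min_coverage)
  }
  if (eligible("NO")) {
    mv["no_avg"] <- annual_mean(series_by_pollutant[["NO"]], min_coverage)
  }
  if (eligible("PM10")) {
    s <- series_by_pollutant[["PM10"]]
    mv["pm10_avg"] <- annual_mean(s, min_coverage)
    dm <- daily_aggregate(s, "mean", min_hours_day, tz_offset)
    mv["pm10_days_gt_50"] <-
      count_daily_exceedances(dm, AQ_THRESHOLDS[["PM10_daily"]])
  }
  if (eligible("PM2.5")) {
    mv["pm25_avg"] <- annual_mean(series_by_pollutant[["PM2.5"]], min_coverage)
  }
  if (eligible("O3")) {
    s <- series_by_pollutant[["O3"]]
    mv["o3_avg"] <- annual_mean(s, min_coverage)
    dm <- daily_aggregate(s, "mean", min_hours_day, tz_offset)
    mv["o3_days_gt_120"] <-
      count_daily_exceedances(dm, AQ_THRESHOLDS[["O3_daily"]])
    dmax <- daily_aggregate(s, "max", min_hours_day, tz_offset)
    if (any(!is.na(dmax))) {
      mv["o3_dailymax_avg"] <- mean(dmax, na.rm = TRUE)
      mv["o3_max_1h"] <- max(dmax, na.rm = TRUE)
    }
    d8 <- max_8h_daily(s, min_hours_window, min_windows_day, tz_offset)
    if (any(!is.na(d8))) mv["o3_max_8h"] <- max(d8, na.rm = TRUE)
  }
  tibble::as_tibble(as.list(mv))
}

#' Annual metric table for many station-years
#'
#' Streams over stations and years: for each background station-year it
#' assembles the hourly series of the pollutants the station measures and
#' computes the metric vector. Traffic and industrial stations are dropped
#' here.
#'
#' @param stations station tibble with columns `station_id`, `type`,
#'   `area_class` (and anything else, carried through by join downstream).
#' @param get_series function `(station_id, pollutant, year) ->
#'   hourly_series or NULL`; `NULL` means the station does not measure that
#'   pollutant that year.
#' @param years integer vector of years.
#' @param pollutants pollutants to attempt (default all).
#' @param ... validity-rule arguments passed to [station_metric_vector()].
#' @return tibble with `station_id`, `year` and the eleven metric columns.
#' @export
station_metrics_table <- function(stations, get_series, years,
                                  pollutants = AQ_POLLUTANTS, ...) {
  bg <- stations[tolower(stations$type) == "background", , drop = FALSE]
  rows <- vector("list", nrow(bg) * length(years))
  k <- 0L
  for (year in years) {
    for (i in seq_len(nrow(bg))) {
      sid <- bg$station_id[i]
      series <- list()
      for (p in pollutants) {
        s <- get_series(sid, p, year)
        if (!is.null(s)) series[[p]] <- s
      }
      if (!length(series)) next
      k <- k + 1L
      rows[[k]] <- dplyr::bind_cols(
        tibble::tibble(station_id = sid, year = as.integer(year)),
        station_metric_vector(series, year, ...)
      )
    }
  }
  if (k == 0L) {
    return(tibble::tibble(
      station_id = character(), year = integer(),
      !!!stats::setNames(rep(list(numeric()), length(AQ_METRICS)), AQ_METRICS)
    ))
  }
  dplyr::bind_rows(rows[seq_len(k)])
}
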