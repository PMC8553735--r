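#' Pollutants, metrics and calendar helpers
#'
#' The pipeline works on five pollutants and eleven annual metrics. Metric
#' identifiers are fixed column names used across every table the package
#' reads or writes.
#'
#' @name aq_schema
#' @keywords internal
NULL

#' Pollutants covered by the pipeline
#' @export
AQ_POLLUTANTS <- c("NO2", "NO", "O3", "PM10", "PM2.5")

#' The eleven annual exposure metrics
#'
#' Annual means for the five pollutants, the NO2 hourly exceedance count
#' (hours > 200 ug/m3), the PM10 and O3 daily exceedance counts (daily means
#' > 50 resp. > 120 ug/m3), the annual mean of the daily O3 maximum, and the
#' annual maxima of the daily 1-h and 8-h O3 statistics.
#' @export
AQ_METRICS <- c(
  "no2_avg", "no2_hours_gt_200",
  "no_avg",
  "pm10_avg", "pm10_days_gt_50",
  "pm25_avg",
  "o3_avg", "o3_days_gt_120", "o3_dailymax_avg", "o3_max_1h", "o3_max_8h"
)

#' Pollutant each metric belongs to
#' @export
AQ_METRIC_POLLUTANT <- c(
  no2_avg = "NO2", no2_hours_gt_200 = "NO2",
  no_avg = "NO",
  pm10_avg = "PM10", pm10_days_gt_50 = "PM10",
  pm25_avg = "PM2.5",
  o3_avg = "O3", o3_days_gt_120 = "O3", o3_dailymax_avg = "O3",
  o3_max_1h = "O3", o3_max_8h = "O3"
)

#' Kind of each metric: "mean", "count_hours", "count_days" or "max"
#' @export
AQ_METRIC_KIND <- c(
  no2_avg = "mean", no2_hours_gt_200 = "count_hours",
  no_avg = "mean",
  pm10_avg = "mean", pm10_days_gt_50 = "count_days",
  pm25_avg = "mean",
  o3_avg = "mean", o3_days_gt_120 = "count_days", o3_dailymax_avg = "mean",
  o3_max_1h = "max", o3_max_8h = "max"
)

#' Metrics computable at daily-or-coarser time resolution
#'
#' These seven metrics can be derived from daily reanalysis fields and are
#' the ones carried through the raster branch of the pipeline.
#' @export
AQ_RASTER_METRICS <- c(
  "no2_avg", "no_avg", "pm10_avg", "pm10_days_gt_50",
  "pm25_avg", "o3_avg", "o3_days_gt_120"
)

#' Anchor map for sub-daily metrics
#'
#' Each metric with sub-daily time resolution is predicted, for gap-filled
#' units, from an annual-mean metric of the same pollutant via a linear
#' relation fitted on observed unit-years.
#' @export
AQ_SUBDAILY_ANCHOR <- c(
  no2_hours_gt_200 = "no2_avg",
  o3_dailymax_avg = "o3_avg",
  o3_max_1h = "o3_avg",
  o3_max_8h = "o3_avg"
)

#' Station area (siting) classes
#' @export
AQ_AREA_CLASSES <- c(
  "urban", "suburban", "rural-nearcity", "rural-regional", "rural",
  "rural-remote"
)

#' Regulatory exceedance thresholds (ug/m3)
#'
#' Hourly NO2 200, daily-mean PM10 50, daily-mean O3 120; exceedance is
#' strict (value > threshold).
#' @export
AQ_THRESHOLDS <- c(NO2_hourly = 200, PM10_daily = 50, O3_daily = 120)

#' @rdname aq_calendar
#' @export
is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Calendar length helpers
#'
#' Number of days (365/366) and hours (8760/8784) in a calendar year.
#'
#' @param year integer year.
#' @return integer scalar (vectorised over `year`).
#' @name aq_calendar
#' @export
days_in_year <- function(year) ifelse(is_leap_year(year), 366L, 365L)

#' @rdname aq_calendar
#' @export
hours_in_year <- function(year) 24L * days_in_year(year)

# calendar cap for a count metric when predictions are bounded
metric_cap <- function(metric, year) {
  switch(AQ_METRIC_KIND[[metric]],
    count_hours = hours_in_year(year),
    count_days = days_in_year(year),
    Inf
  )
}

# round half away from zero (predictions are non-negative here)
round_half_up <- function(x) floor(x + 0.5)
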