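# Independent brute-force reimplementation of the annual metrics, written
# as explicit loops over hours, days and windows. Deliberately shares no
# code with the package implementation.

oracle_coverage <- function(v) {
  n_ok <- 0L
  for (x in v) if (!is.na(x)) n_ok <- n_ok + 1L
  n_ok / length(v)
}

oracle_annual_mean <- function(v, min_coverage = 0.8) {
  if (oracle_coverage(v) < min_coverage) return(NA_real_)
  s <- 0; n <- 0L
  for (x in v) if (!is.na(x)) { s <- s + x; n <- n + 1L }
  s / n
}

oracle_hourly_exceedances <- function(v, threshold, min_coverage = 0.8) {
  if (oracle_coverage(v) < min_coverage) return(NA_integer_)
  cnt <- 0L
  for (x in v) if (!is.na(x) && x > threshold) cnt <- cnt + 1L
  cnt
}

oracle_daily <- function(v, stat, min_hours = 18L) {
  nd <- length(v) %/% 24L
  out <- rep(NA_real_, nd)
  for (d in seq_len(nd)) {
    hrs <- v[((d - 1L) * 24L + 1L):(d * 24L)]
    ok <- hrs[!is.na(hrs)]
    if (length(ok) >= min_hours) out[d] <- stat(ok)
  }
  out
}

oracle_daily_exceedances <- function(daily, threshold) {
  cnt <- 0L
  for (x in daily) if (!is.na(x) && x > threshold) cnt <- cnt + 1L
  cnt
}

oracle_max8h_daily <- function(v, min_hours_window = 6L,
                               min_windows_day = 18L) {
  nd <- length(v) %/% 24L
  out <- rep(NA_real_, nd)
  for (d in seq_len(nd)) {
    means <- rep(NA_real_, 24L)
    for (h in seq_len(24L)) {
      end <- (d - 1L) * 24L + h
      idx <- (end - 7L):end
      win <- v[idx[idx >= 1L]]
      win <- win[!is.na(win)]
      if (length(win) >= min_hours_window) means[h] <- mean(win)
    }
    ok <- means[!is.na(means)]
    if (length(ok) >= min_windows_day) out[d] <- max(ok)
  }
  out
}

# all eleven metrics from per-pollutant hourly vectors (full-year length)
oracle_metric_vector <- function(values_by_pollutant, year) {
  out <- stats::setNames(rep(NA_real_, length(AQ_METRICS)), AQ_METRICS)
  g <- function(p) values_by_pollutant[[p]]
  if (!is.null(g("NO2"))) {
    out["no2_avg"] <- oracle_annual_mean(g("NO2"))
    out["no2_hours_gt_200"] <- oracle_hourly_exceedances(g("NO2"), 200)
  }
  if (!is.null(g("NO"))) out["no_avg"] <- oracle_annual_mean(g("NO"))
  if (!is.null(g("PM10"))) {
    out["pm10_avg"] <- oracle_annual_mean(g("PM10"))
    if (!is.na(out["pm10_avg"])) {
      out["pm10_days_gt_50"] <-
        oracle_daily_exceedances(oracle_daily(g("PM10"), mean), 50)
    }
  }
  if (!is.null(g("PM2.5"))) out["pm25_avg"] <- oracle_annual_mean(g("PM2.5"))
  if (!is.null(g("O3"))) {
    v <- g("O3")
    out["o3_avg"] <- oracle_annual_mean(v)
    if (!is.na(out["o3_avg"])) {
      out["o3_days_gt_120"] <-
        oracle_daily_exceedances(oracle_daily(v, mean), 120)
      dmax <- oracle_daily(v, max)
      if (any(!is.na(dmax))) {
        out["o3_dailymax_avg"] <- mean(dmax[!is.na(dmax)])
        out["o3_max_1h"] <- max(dmax[!is.na(dmax)])
      }
      d8 <- oracle_max8h_daily(v)
      if (any(!is.na(d8))) out["o3_max_8h"] <- max(d8[!is.na(d8)])
    }
  }
  out
}

# random full-year test vector with spikes crossing the exceedance
# thresholds and patchy missingness
random_hourly_values <- function(year, base = 40, missing_fraction = 0.05) {
  H <- hours_in_year(year)
  v <- pmax(0, base + stats::rnorm(H, 0, 15))
  spikes <- sample.int(H, round(0.02 * H))
  v[spikes] <- v[spikes] + stats::runif(length(spikes), 50, 250)
  if (missing_fraction > 0) {
    v[sample.int(H, round(missing_fraction * H))] <- NA_real_
  }
  v
}
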