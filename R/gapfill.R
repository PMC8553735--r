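#' Fit a linear scaling function
#'
#' Ordinary least-squares line mapping reanalysis-derived unit values onto
#' observation-derived ones, pooled across years within one metric and
#' scenario. Requires at least three complete pairs and non-degenerate
#' variance in the predictor.
#'
#' @param x reanalysis-derived values (predictor).
#' @param y observation-derived values (response).
#' @param metric,scenario labels stored on the fit.
#' @return object of class `aq_scaling`: `metric`, `scenario`, `slope`,
#'   `intercept`, `n`, `r` (Pearson correlation; `NA` when `y` is
#'   constant).
#' @export
fit_scaling <- function(x, y, metric = NA_character_,
                        scenario = NA_character_) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop("unidentifiable scaling: needs at least 3 pairs, got ", n,
         call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("unidentifiable scaling: degenerate predictor variance",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  r <- suppressWarnings(stats::cor(x, y))
  structure(
    list(metric = metric, scenario = scenario,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         n = n, r = r),
    class = "aq_scaling"
  )
}

#' @export
print.aq_scaling <- function(x, ...) {
  cat(sprintf("<aq_scaling> %s / %s: y = %.4f x + %.4f (n = %d, r = %.3f)\n",
              x$metric, x$scenario, x$slope, x$intercept, x$n, x$r))
  invisible(x)
}

#' Apply a scaling function to reanalysis values
#'
#' Predictions are clipped at zero; exceedance-count metrics are
#' additionally rounded half-up and capped at the calendar maximum (hours
#' or days in the year).
#'
#' @param fn an `aq_scaling` (or `aq_subdaily`) fit.
#' @param x reanalysis-derived (or anchor) values.
#' @param year calendar year, needed to cap count metrics.
#' @param metric metric id (defaults to the fit's metric).
#' @return gap-filled values.
#' @export
apply_scaling <- function(fn, x, year, metric = fn$metric) {
  if (is.null(fn$n) || fn$n < 3L) {
    stop("scaling function unusable (n < 3)", call. = FALSE)
  }
  pred <- pmax(0, fn$slope * x + fn$intercept)
  if (!is.na(metric) && AQ_METRIC_KIND[[metric]] %in%
        c("count_hours", "count_days")) {
    pred <- pmin(round_half_up(pred), metric_cap(metric, year))
  }
  pred
}

#' Fit a sub-daily-from-annual-mean relation
#'
#' The four metrics with sub-daily time resolution cannot be computed from
#' daily reanalysis fields; for gap-filled units they are predicted from an
#' annual-mean metric of the same pollutant (NO2 hourly exceedances from
#' the NO2 annual mean; the three O3 peak statistics from the O3 annual
#' mean) via an OLS line fitted on observed unit-years. When the target is
#' identically constant (e.g. no exceedances anywhere) a degenerate fit
#' with slope 0 and intercept equal to that constant is returned.
#'
#' @param anchor observed anchor-metric values.
#' @param target observed target-metric values.
#' @param target_metric one of `names(AQ_SUBDAILY_ANCHOR)`.
#' @param scenario label stored on the fit.
#' @return object of class `c("aq_subdaily", "aq_scaling")` with an extra
#'   `anchor` field.
#' @export
fit_subdaily <- function(anchor, target, target_metric,
                         scenario = NA_character_) {
  if (!target_metric %in% names(AQ_SUBDAILY_ANCHOR)) {
    stop("not a sub-daily metric: ", target_metric, call. = FALSE)
  }
  ok <- !is.na(anchor) & !is.na(target)
  if (sum(ok) >= 3L && (stats::var(target[ok]) == 0 ||
                          stats::var(anchor[ok]) == 0)) {
    fn <- structure(
      list(metric = target_metric, scenario = scenario, slope = 0,
           intercept = mean(target[ok]), n = sum(ok), r = NA_real_),
      class = "aq_scaling"
    )
  } else {
    fn <- fit_scaling(anchor, target, target_metric, scenario)
  }
  fn$anchor <- AQ_SUBDAILY_ANCHOR[[target_metric]]
  class(fn) <- c("aq_subdaily", class(fn))
  fn
}

#' Gap-fill one unit-year
#'
#' For each metric missing from the observed vector: daily-or-coarser
#' metrics are predicted by the metric's scaling function from the unit's
#' vectorized reanalysis value; sub-daily metrics by their sub-daily
#' relation from the (observed or just gap-filled) anchor metric. Every
#' metric receives a provenance flag.
#'
#' @param observed named numeric vector on the `AQ_METRICS` schema
#'   (`NA` = missing).
#' @param reanalysis named numeric vector of the unit's vectorized values
#'   for `AQ_RASTER_METRICS`.
#' @param scalings named list of `aq_scaling`, one per raster metric.
#' @param subdaily named list of `aq_subdaily`, one per sub-daily metric.
#' @param year calendar year.
#' @return list with `values` (named, complete) and `provenance` (named,
#'   `"observed"` or `"reanalysis-derived"`).
#' @export
gapfill_unit_year <- function(observed, reanalysis, scalings, subdaily,
                              year) {
  values <- stats::setNames(rep(NA_real_, length(AQ_METRICS)), AQ_METRICS)
  values[names(observed)] <- observed
  provenance <- stats::setNames(
    ifelse(is.na(values), "reanalysis-derived", "observed"), AQ_METRICS)

  for (m in AQ_RASTER_METRICS) {
    if (!is.na(values[[m]])) next
    if (!m %in% names(reanalysis) || is.na(reanalysis[[m]])) {
      stop("incomplete field: no reanalysis value for ", m, call. = FALSE)
    }
    values[[m]] <- apply_scaling(scalings[[m]], reanalysis[[m]], year, m)
  }
  for (m in names(AQ_SUBDAILY_ANCHOR)) {
    if (!is.na(values[[m]])) next
    anchor <- AQ_SUBDAILY_ANCHOR[[m]]
    values[[m]] <- apply_scaling(subdaily[[m]], values[[anchor]], year, m)
  }
  list(values = values, provenance = provenance)
}

#' Fit all scaling functions and sub-daily relations for one scenario
#'
#' Scaling fits pair, per metric, the vectorized reanalysis values with the
#' observation-derived unit values over all unit-years where the latter
#' exist; sub-daily fits pair observed anchor and target metrics.
#'
#' @param observed long tibble from [aggregate_units()] (one scenario).
#' @param reanalysis tibble from [reanalysis_unit_values()] stacked over
#'   years.
#' When a metric's reanalysis predictor is degenerate (no variance across
#' unit-years — typically an exceedance count that is zero everywhere), a
#' strict OLS fit is unidentifiable; the stage then falls back to an
#' intercept-only model (slope 0, intercept the mean observed value),
#' which predicts the observed mean for every gap-filled unit.
#'
#' @return list with `scalings`, `subdaily` (named lists of fits) and
#'   `diagnostics` (tibble `metric`, `scenario`, `kind`, `slope`,
#'   `intercept`, `n`, `r`).
#' @export
fit_gapfill_models <- function(observed, reanalysis) {
  scenario <- unique(observed$scenario)
  stopifnot(length(scenario) == 1L)
  fit_or_fallback <- function(x, y, metric) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) >= 3L && stats::var(x[ok]) == 0) {
      structure(
        list(metric = metric, scenario = scenario, slope = 0,
             intercept = mean(y[ok]), n = sum(ok), r = NA_real_),
        class = "aq_scaling"
      )
    } else {
      fit_scaling(x, y, metric, scenario)
    }
  }
  scalings <- list()
  for (m in AQ_RASTER_METRICS) {
    obs <- observed[observed$metric == m, c("nuts_code", "year", "value")]
    rea <- reanalysis[reanalysis$metric == m,
                      c("nuts_code", "year", "value")]
    pairs <- dplyr::inner_join(rea, obs, by = c("nuts_code", "year"),
                               suffix = c("_cams", "_obs"))
    scalings[[m]] <- fit_or_fallback(pairs$value_cams, pairs$value_obs, m)
  }
  subdaily <- list()
  wide <- tidyr::pivot_wider(
    observed[, c("nuts_code", "year", "metric", "value")],
    names_from = "metric", values_from = "value"
  )
  for (m in names(AQ_SUBDAILY_ANCHOR)) {
    anchor <- AQ_SUBDAILY_ANCHOR[[m]]
    subdaily[[m]] <- fit_subdaily(wide[[anchor]], wide[[m]], m, scenario)
  }
  diagnostics <- dplyr::bind_rows(c(
    lapply(unname(scalings), function(f) tibble::tibble(
      metric = f$metric, scenario = f$scenario, kind = "scaling",
      anchor = NA_character_, slope = f$slope, intercept = f$intercept,
      n = f$n, r = f$r)),
    lapply(unname(subdaily), function(f) tibble::tibble(
      metric = f$metric, scenario = f$scenario, kind = "subdaily",
      anchor = f$anchor, slope = f$slope, intercept = f$intercept,
      n = f$n, r = f$r))
  ))
  list(scalings = scalings, subdaily = subdaily, diagnostics = diagnostics)
}

#' Gap-fill a whole scenario table
#'
#' Applies [gapfill_unit_year()] to every unit-year of one scenario,
#' producing a complete long table with provenance. Checks the count of
#' violations of the ordering `o3_max_8h <= o3_max_1h` among gap-filled
#' unit-years (two independent linear fits do not guarantee it) and
#' attaches it as the `"ordering_violations"` attribute.
#'
#' @param observed long tibble from [aggregate_units()] (one scenario).
#' @param reanalysis tibble from [reanalysis_unit_values()] stacked over
#'   years.
#' @param models fits from [fit_gapfill_models()] (refitted when `NULL`).
#' @return long tibble `nuts_code`, `year`, `scenario`, `metric`, `value`,
#'   `provenance`, `station_types`, `ratified`.
#' @export
gapfill_table <- function(observed, reanalysis, models = NULL) {
  if (is.null(models)) models <- fit_gapfill_models(observed, reanalysis)
  scenario <- unique(observed$scenario)

  obs_wide <- tidyr::pivot_wider(
    observed[, c("nuts_code", "year", "metric", "value")],
    names_from = "metric", values_from = "value"
  )
  rea_wide <- tidyr::pivot_wider(
    reanalysis[, c("nuts_code", "year", "metric", "value")],
    names_from = "metric", values_from = "value"
  )
  keys <- obs_wide[, c("nuts_code", "year")]
  rea_wide <- dplyr::left_join(keys, rea_wide, by = c("nuts_code", "year"))
  obs_mat <- as.matrix(obs_wide[, AQ_METRICS])
  rea_cols <- intersect(AQ_RASTER_METRICS, names(rea_wide))
  rea_mat <- as.matrix(rea_wide[, rea_cols])

  n_viol <- 0L
  val_mat <- matrix(NA_real_, nrow(keys), length(AQ_METRICS),
                    dimnames = list(NULL, AQ_METRICS))
  prov_mat <- matrix(NA_character_, nrow(keys), length(AQ_METRICS),
                     dimnames = list(NULL, AQ_METRICS))
  for (i in seq_len(nrow(keys))) {
    gf <- gapfill_unit_year(obs_mat[i, ], rea_mat[i, ],
                            models$scalings, models$subdaily,
                            keys$year[i])
    filled <- gf$provenance == "reanalysis-derived"
    if (any(filled[c("o3_max_1h", "o3_max_8h")]) &&
          gf$values[["o3_max_8h"]] > gf$values[["o3_max_1h"]]) {
      n_viol <- n_viol + 1L
    }
    val_mat[i, ] <- gf$values
    prov_mat[i, ] <- gf$provenance
  }
  out <- tibble::tibble(
    nuts_code = rep(keys$nuts_code, each = length(AQ_METRICS)),
    year = rep(keys$year, each = length(AQ_METRICS)),
    scenario = scenario,
    metric = rep(AQ_METRICS, nrow(keys)),
    value = as.vector(t(val_mat)),
    provenance = as.vector(t(prov_mat))
  )
  out <- dplyr::left_join(
    out,
    observed[, c("nuts_code", "year", "metric", "station_types",
                 "ratified")],
    by = c("nuts_code", "year", "metric")
  )
  out$station_types[out$provenance != "observed"] <- ""
  out$ratified[out$provenance != "observed"] <- NA
  attr(out, "ordering_violations") <- n_viol
  out
}

#' Regional-average baseline gap filling
#'
#' Fills each missing unit-metric with the mean of the observed values in
#' the unit's region (NUTS-2-like grouping); remains missing when the whole
#' region lacks observations. Kept as a comparison baseline: it produces
#' spatial uniformity across each region regardless of unit character.
#'
#' @param observed long tibble from [aggregate_units()].
#' @param units an `aq_units` tibble with a `region` column.
#' @return `observed` with filled values and a `provenance` column
#'   (`"observed"` / `"regional-average"` / `NA` when unfillable).
#' @export
baseline_regional <- function(observed, units) {
  df <- dplyr::left_join(observed,
                         units[, c("nuts_code", "region")],
                         by = "nuts_code")
  df <- df |>
    dplyr::group_by(.data$region, .data$year, .data$metric) |>
    dplyr::mutate(regional_mean = mean(.data$value, na.rm = TRUE)) |>
    dplyr::ungroup()
  filled <- is.na(df$value) & is.finite(df$regional_mean)
  df$provenance <- dplyr::case_when(
    !is.na(df$value) ~ "observed",
    filled ~ "regional-average",
    TRUE ~ NA_character_
  )
  df$value[filled] <- df$regional_mean[filled]
  df[, setdiff(names(df), c("region", "regional_mean"))]
}

#' Nearest-neighbour baseline gap filling
#'
#' Fills each missing unit-metric with the value of the nearest unit (by
#' great-circle centroid distance) holding an observed value for that
#' metric-year; ties break to the lower unit code. Kept as a comparison
#' baseline: an unmonitored rural unit adjacent to a monitored city
#' inherits the city's exposure value — the artifact that motivates the
#' reanalysis-based approach.
#'
#' @param observed long tibble from [aggregate_units()].
#' @param units an `aq_units` tibble.
#' @return `observed` with filled values and a `provenance` column.
#' @export
baseline_nearest <- function(observed, units) {
  cen <- unit_centroids(units)
  dmat <- geosphere::distm(as.matrix(cen[, c("lon", "lat")]))
  rownames(dmat) <- colnames(dmat) <- cen$nuts_code
  code_order <- order(cen$nuts_code)

  out <- observed
  out$provenance <- ifelse(is.na(out$value), NA_character_, "observed")
  miss <- which(is.na(out$value))
  if (!length(miss)) return(out)
  for (grp in split(miss, list(out$metric[miss], out$year[miss]),
                    drop = TRUE)) {
    m <- out$metric[grp[1]]; y <- out$year[grp[1]]
    donors <- observed[observed$metric == m & observed$year == y &
                         !is.na(observed$value), ]
    if (!nrow(donors)) next
    # order donors by code so which.min on ties picks the lower code
    donors <- donors[order(donors$nuts_code), ]
    for (i in grp) {
      d <- dmat[out$nuts_code[i], donors$nuts_code]
      j <- which(d <= min(d) + 1e-6)[1]
      out$value[i] <- donors$value[j]
      out$provenance[i] <- "nearest-neighbour"
    }
  }
  out
}
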