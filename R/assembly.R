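#' Merge gap-filled scenario tables into the final exposure records
#'
#' Validates that every scenario and year is present, every metric value is
#' non-missing, and keys are unique, then pivots to one record per
#' (unit, year, scenario) with the eleven metric columns plus per-metric
#' provenance, ratification and station-type columns.
#'
#' @param filled_tables list of long tables from [gapfill_table()], one per
#'   scenario.
#' @param units an `aq_units` tibble (supplies `nuts_name`).
#' @param years years that must be present.
#' @return tibble of exposure records, ordered by (code, year, scenario);
#'   metric columns `<metric>`, provenance `prov_<metric>`, ratification
#'   `ratified_<metric>`, station types `types_<metric>`.
#' @export
assemble <- function(filled_tables, units, years) {
  long <- dplyr::bind_rows(filled_tables)
  have <- unique(long[, c("scenario", "year")])
  want <- tidyr::expand_grid(scenario = AQ_SCENARIOS,
                             year = as.integer(years))
  missing <- dplyr::anti_join(want, have, by = c("scenario", "year"))
  if (nrow(missing)) {
    stop("incomplete pipeline output: missing ",
         paste(missing$scenario, missing$year, collapse = ", "),
         call. = FALSE)
  }
  long <- long[long$year %in% years, ]
  if (anyNA(long$value)) {
    stop("incomplete pipeline output: ", sum(is.na(long$value)),
         " missing metric values after gap filling", call. = FALSE)
  }

  wide_val <- tidyr::pivot_wider(
    long[, c("nuts_code", "year", "scenario", "metric", "value")],
    names_from = "metric", values_from = "value")
  wide_prov <- tidyr::pivot_wider(
    long[, c("nuts_code", "year", "scenario", "metric", "provenance")],
    names_from = "metric", values_from = "provenance",
    names_prefix = "prov_")
  wide_rat <- tidyr::pivot_wider(
    long[, c("nuts_code", "year", "scenario", "metric", "ratified")],
    names_from = "metric", values_from = "ratified",
    names_prefix = "ratified_")
  wide_typ <- tidyr::pivot_wider(
    long[, c("nuts_code", "year", "scenario", "metric", "station_types")],
    names_from = "metric", values_from = "station_types",
    names_prefix = "types_")

  key <- c("nuts_code", "year", "scenario")
  rec <- wide_val |>
    dplyr::left_join(wide_prov, by = key) |>
    dplyr::left_join(wide_rat, by = key) |>
    dplyr::left_join(wide_typ, by = key) |>
    dplyr::left_join(units[, c("nuts_code", "nuts_name")],
                     by = "nuts_code")
  if (anyDuplicated(rec[, key])) {
    stop("duplicate (unit, year, scenario) keys", call. = FALSE)
  }
  n_expect <- nrow(units) * length(AQ_SCENARIOS) * length(years)
  if (nrow(rec) != n_expect) {
    stop("incomplete pipeline output: ", nrow(rec), " records, expected ",
         n_expect, call. = FALSE)
  }
  rec <- rec[order(rec$nuts_code, rec$year, rec$scenario), ]
  rec[, c("nuts_code", "nuts_name", "year", "scenario", AQ_METRICS,
          paste0("prov_", AQ_METRICS), paste0("ratified_", AQ_METRICS),
          paste0("types_", AQ_METRICS))]
}

# fixed decimal formatting of a metric column for file output
format_metric <- function(x, metric, year) {
  if (AQ_METRIC_KIND[[metric]] %in% c("count_hours", "count_days")) {
    sprintf("%d", pmin(as.integer(round_half_up(x)),
                       metric_cap(metric, year)))
  } else {
    sprintf("%.3f", x)
  }
}

#' Write the three output files
#'
#' Writes the main values file, the ratification-status file and the
#' station-types file. All three share the identical key and per-metric
#' column layout and deterministic row order (code, year, scenario).
#' Means use fixed 3-decimal formatting; exceedance counts are rounded
#' half-up to integers here (and capped at the calendar maximum).
#' Ratification cells are `yes`/`no`, `n/a` for reanalysis-derived values;
#' station-type cells list the contributing area classes
#' (semicolon-separated), empty for reanalysis-derived values.
#'
#' @param records tibble from [assemble()].
#' @param output_dir directory (created if needed).
#' @param basename file stem (default `"exposure"`).
#' @return invisibly, the three file paths.
#' @export
write_outputs <- function(records, output_dir, basename = "exposure") {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  key <- records[, c("nuts_code", "nuts_name", "year", "scenario")]

  vals <- key
  for (m in AQ_METRICS) {
    vals[[m]] <- mapply(format_metric, records[[m]], m, records$year)
  }
  rat <- key
  for (m in AQ_METRICS) {
    r <- records[[paste0("ratified_", m)]]
    rat[[m]] <- ifelse(is.na(r), "n/a", ifelse(r, "yes", "no"))
  }
  typ <- key
  for (m in AQ_METRICS) {
    typ[[m]] <- records[[paste0("types_", m)]]
  }

  paths <- file.path(output_dir, paste0(basename, c(
    ".csv", "_Ratified.csv", "_StationTypes.csv")))
  readr::write_csv(vals, paths[1])
  readr::write_csv(rat, paths[2])
  readr::write_csv(typ, paths[3])
  invisible(paths)
}

#' Read a written exposure values file back
#'
#' @param path the main values CSV from [write_outputs()].
#' @return tibble with typed metric columns.
#' @export
read_exposure_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    nuts_code = readr::col_character(),
                    nuts_name = readr::col_character(),
                    year = readr::col_integer(),
                    scenario = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
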