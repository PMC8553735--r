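Package: aqexposure
Title: Construction of Annual Air-Quality Exposure Datasets on Administrative Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds long-term ambient air-pollution exposure datasets at the
    administrative-unit (NUTS-3) level from hourly monitoring-station data and
    a coarse gridded reanalysis. Computes the eleven annual air-quality metrics
    used in EU exposure assessment (annual means for NO2, NO, O3, PM10, PM2.5
    and the associated hourly/daily exceedance and ozone peak statistics) with
    an 80 percent data-capture rule, aggregates station values to units under
    three station-siting scenarios (average, urban-preferred, remote-preferred),
    and fills unmonitored units by linearly scaling reanalysis-derived zonal
    values to the observation-derived ones. Includes a synthetic-data generator
    with known ground truth (units, station networks, hourly series, rasters)
    so the full pipeline is testable without external downloads, plus the two
    baseline gap-filling strategies (regional average, nearest neighbour) for
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
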