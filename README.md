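# aqexposure

Construction of long-term air-quality exposure datasets at the
administrative-unit level, for epidemiologists and environmental-health
researchers who need yearly ambient-pollution metrics per county rather
than per monitoring station.

Air-quality monitoring networks are sparse and uneven: in Germany, fewer
than half of the 402 NUTS-3 units (counties) hold a monitoring station for
any given pollutant. `aqexposure` builds a complete unit × year × scenario
table of eleven annual metrics for NO₂, NO, O₃, PM₁₀ and PM₂.₅ from two
inputs — hourly station observations and a coarse (0.75°) 3-hourly
gridded reanalysis — and documents, per metric, whether each value is
observed or reanalysis-derived.

## The method

**Station metrics.** From each station-pollutant-year hourly series with
annual data capture ≥ 80 % (series below the threshold are discarded
entirely, to avoid seasonal bias), eleven metrics are computed: the five
annual means; the count of hours with NO₂ > 200 µg m⁻³; the counts of days
with daily-mean PM₁₀ > 50 and O₃ > 120 µg m⁻³; the annual mean of the
daily O₃ maximum; and the annual maxima of the daily 1-h and 8-h running
mean O₃ (a day is valid with ≥ 18/24 hours; an 8-h window with ≥ 6/8
hours). Only *background* stations are used; traffic and industrial sites
are excluded as unrepresentative of long-term ambient exposure.

**Unit aggregation.** Station values are averaged within each unit under
three scenarios: `average` (all background stations), `urban` and
`remote`, which use only the stations of the most preferred siting class
present, with strict fallback down the preference order
(urban → suburban → rural-near-city → rural-regional → rural, and its
reverse).

**Gap filling.** The reanalysis is averaged to daily fields; every metric
computable at daily-or-coarser resolution is evaluated per grid cell,
upscaled from 0.75° to 0.01° by value replication, and clipped
(area-weighted mean) to each unit. Per metric and scenario, an ordinary
least-squares scaling line maps these vectorized reanalysis values onto the
observation-derived unit values,

  ŷ_u = β₀ + β₁ · x_u ,

and fills every unmonitored unit-year. Sub-daily metrics (the NO₂ hourly
exceedance count and the three O₃ peak statistics) are predicted from an
annual-mean metric of the same pollutant via a second linear relation
fitted on observed unit-years. Two rejected baselines — regional (NUTS-2)
averaging and nearest-neighbour copying — are included for comparison.

A synthetic-data generator produces units, station networks, hourly series
and rasters with known ground truth (including an affine link between the
raster field and the unit truth), so every stage is testable without
external downloads.

## Worked example

```r
library(aqexposure)

cfg <- aq_config(n_units = 20, years = 2018,
                 coverage = c(NO2 = 0.5, NO = 0.5, O3 = 0.5,
                              PM10 = 0.5, "PM2.5" = 0.35),
                 seed = 1)
res <- run_pipeline(cfg)
#> [stations] 25 stations (21 background)
#> [coverage] NO2   units covered: min 10, max 10 (of 20)
#> ...
#> [gapfill] average: 107 of 220 unit-year-metric values observed
#> [assemble] 60 records (20 units x 3 scenarios x 1 years)

res$records[res$records$nuts_code == "DE001",
            c("nuts_code", "scenario", "no2_avg", "o3_avg", "o3_max_8h")]
#>   nuts_code scenario no2_avg o3_avg o3_max_8h
#> 1 DE001     average     18.8   44.2      129.
#> 2 DE001     remote      18.4   50.8      148.
#> 3 DE001     urban       19.2   37.6      110.
```

Half of the 20 units are monitored; the other half are filled from the
scaled reanalysis. The three rows show the scenario effect: the urban
scenario raises NO₂ and lowers O₃ (titration near sources), the remote
scenario does the opposite. `res$diagnostics` holds every fitted scaling
line (slope, intercept, n, correlation) for audit — for example the O₃
daily-maximum relation `o3_dailymax_avg ≈ 1.13 · o3_avg + 4.28` fitted on
the ten observed unit-years. `write_outputs(res$records, "out/")` writes
the values file plus the ratification-status and station-types files,
which share the same layout.

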