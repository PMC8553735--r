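---
title: "Building unit-level air-quality exposure datasets: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building unit-level air-quality exposure datasets: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqexposure)
```

## The problem

Epidemiological studies of long-term air-pollution effects need exposure
values per administrative unit (here NUTS-3, the German *Landkreis* /
*Kreisfreie Stadt* level, 402 units) and per year, for the pollutants that
dominate health impact assessment: NO₂, NO, O₃, PM₁₀ and PM₂.₅. Monitoring
networks cannot supply this directly: station siting follows pollution
hot-spots, population and funding, so fewer than half of the units hold a
station for any pollutant, and the monitored subset is not spatially
representative. This package implements a reproducible pipeline that (i)
condenses hourly station data to annual metrics under explicit validity
rules, (ii) aggregates stations to units under three siting scenarios, and
(iii) fills unmonitored units by linearly rescaling a coarse atmospheric
reanalysis to the observation scale.

## Annual metrics and validity rules

Eleven metrics are computed per station-year (`AQ_METRICS`): annual means
of the five pollutants; hours with NO₂ > 200 µg m⁻³; days with daily-mean
PM₁₀ > 50 µg m⁻³ and O₃ > 120 µg m⁻³; the annual mean of the daily O₃
maximum; and the annual maxima of the daily 1-h and running 8-h mean O₃.
All exceedances are strict (`>`), matching the regulatory reading of
"over". The thresholds live in one place (`AQ_THRESHOLDS`) and in the
pipeline configuration.

The only annual eligibility rule is data capture: a station-year enters no
metric unless at least 80 % of the year's hours (8760, 8784 in leap years)
are non-missing — incomplete series would otherwise import a seasonal
bias, since missingness in practice clusters in maintenance periods. The
rule applies to the actual calendar length of the year.

Sub-annual validity is not fixed by the 80 % rule, so the package adopts
the conventions used in EU air-quality reporting and exposes them as
arguments: a calendar day is valid with ≥ 18 of 24 hourly values
(`min_hours_day`); an 8-hour running mean is valid with ≥ 6 of its 8 hours
(`min_hours_window`); a day's 8-h statistic is valid when ≥ 18 of the 24
windows *ending* in that day are valid (window-end attribution,
`min_windows_day`). Day boundaries are UTC by default; `tz_offset` shifts
them for networks reporting in local standard time. Missing values are
encoded as `NA`, never 0, so downstream stages can distinguish "no
exceedances" from "not measured".

## Scenarios and unit aggregation

Stations are geo-located into units by point-in-polygon; points on shared
edges resolve to the first unit in code order (a documented, deterministic
tie-break). Only background stations participate; traffic and industrial
sites are filtered out. Three unit-level averages are produced:

* **average** — unweighted mean over all background stations with a value;
* **urban** — stations of the most urban siting class present, in
  preference order urban, suburban, rural-near-city, rural-regional,
  rural;
* **remote** — the reverse preference.

"Preference, though not exclusiveness" is read as *strict fallback*: only
the best non-empty class contributes, and later classes are used solely
when earlier ones have no value. A weighted blend would be the other
defensible reading; strict fallback is the minimal one and makes the three
scenarios coincide exactly on single-class units, a property the tests
assert. Selection is per metric, so a station that fails the capture rule
for PM₂.₅ can still anchor the unit's NO₂ value. The class `rural-remote`
(present in newer network metadata but absent from the printed preference
orders) is slotted at the remote end: last under `urban`, first under
`remote`. Averages are unweighted; exceedance-count means are kept as
fractional reals internally and rounded half-up only when files are
written.

`compare_scenarios()` quantifies scenario sensitivity as the 95th
percentile (linear-interpolation quantile) of |scenario − average| /
average over unit-years with a positive average value; zero-average
unit-years are excluded and counted. On real German data this quantity is
of order 7 %; on the default synthetic world it is larger (≈ 21 % for the
NO₂ mean) because the generator's urban increment (±30 %) is deliberately
strong so that scenario selection is sharply testable.

## The reanalysis branch

The gridded input is a 3-hourly concentration field at 0.75° resolution.
Metrics with daily-or-coarser time resolution — the five annual means and
the two daily exceedance counts — are computed per grid cell after
averaging the eight timesteps of each day. Each per-cell metric raster is
then upscaled to 0.01° by pure value replication (75 × 75 children per
cell, no interpolation) and clipped to each unit as the mean over fine
cells whose centers fall inside the polygon.

Cell-center membership at 0.01° approximates the exact polygon-cell
intersection to within the boundary-cell fraction (< 1 % for county-sized
units); the tests verify that halving the fine resolution changes clip
values by less than 1 %, that a constant field clips to the constant, and
that a polygon congruent with one coarse cell returns exactly that cell's
value. Fine cells use half-open membership (`[min, max)`, closed at the
raster's outer edge), so the units partition the fine grid with no double
counting. Grid registration is cell-center; values are treated as
cell-constant, which the replication rule forces anyway.

## Gap filling

For each metric and scenario, an ordinary least-squares line with
intercept maps the vectorized reanalysis values onto the observed unit
values, pooled across all years (the alternative — one fit per year — is
noted as an open choice; pooling uses the available pairs most
efficiently and matches a per-metric, per-scenario reading of the
procedure). A fit requires at least three pairs and non-degenerate
predictor variance. When the predictor is degenerate — typically an
exceedance count that is zero in every unit — the stage falls back to an
intercept-only model predicting the mean observed value; with a constant
observed response this reduces to predicting that constant.

Predictions are clipped at zero; count metrics are additionally rounded
half-up and capped at the calendar maximum. Sub-daily metrics cannot be
computed from daily fields, so they are predicted from an annual-mean
anchor of the same pollutant (`AQ_SUBDAILY_ANCHOR`): NO₂ hourly
exceedances from the NO₂ mean, and the three O₃ peak statistics from the
O₃ mean, using relations fitted on observed unit-years and applied to the
observed-or-gap-filled anchor. Because the O₃ 1-h and 8-h maxima are
filled by two independent linear fits, the ordering `o3_max_8h ≤
o3_max_1h` is not guaranteed for gap-filled units; the pipeline counts
violations and reports them (`ordering_violations`) rather than silently
re-ordering.

Every output value carries a provenance flag (`observed` /
`reanalysis-derived`); ratification status and contributing station
classes are tracked per metric and written to metadata files that mirror
the main file's layout, with `n/a` / empty cells for reanalysis-derived
values.

Two baseline strategies are retained for comparison, not production:
regional (NUTS-2) averaging, which flattens whole regions to one value,
and nearest-neighbour copying, which assigns a monitored city's exposure
verbatim to its unmonitored rural neighbour — the artifact that motivates
the reanalysis route. Nearest-neighbour distances are great-circle
(haversine) between unit centroids with ties broken to the lower code.

## The synthetic generator

The generator exists so that every stage has a testable ground truth; its
defaults emulate the study conditions of the German network.

* **Units**: a rectangular tiling of a Germany-like bounding box
  (default 402 units), codes `DE001`… with a NUTS-2-like region grouping.
  Real county shapes are irregular; rectangles keep geometry exact while
  preserving everything the pipeline actually uses (containment, area
  weights, adjacency scale).
* **Truth field**: per pollutant, a typical German annual-mean base level
  (NO₂ 18, NO 10, O₃ 48, PM₁₀ 19, PM₂.₅ 12 µg m⁻³) with a mild (±8 %)
  smooth spatial gradient, optional per-unit lognormal scatter (6 %), and
  a 1 %-per-year decline for NO₂/NO/PM.
* **Stations**: per pollutant, a random unit subset at the configured
  coverage fraction (defaults: the network's maximal observed coverage,
  e.g. 197/402 for NO₂, 110/402 for PM₂.₅) receives background stations;
  some units also get traffic/industrial stations that downstream
  filtering must reject. Urban-class stations sample the unit truth times
  an increment (+30 % for NO₂/NO/PM, −30 % for O₃, graded across classes),
  which is what makes the three scenarios differ measurably.
* **Hourly series**: truth × a unit-annual-mean shape (seasonal sinusoid,
  winter-peaking except summer-peaking O₃; diurnal sinusoid; lognormal
  day-to-day episode factor, sd 0.4) plus Gaussian noise (sd 3 µg m⁻³),
  clipped at zero, with 5 % missingness (uniform, or one contiguous block
  for stress tests). The episode factor is what makes daily exceedance
  thresholds attainable at realistic annual means. All shape factors are
  normalised to unit annual mean, so the noiseless annual mean equals the
  truth exactly.
* **Rasters**: per cell, an affine function (default slope 0.8, intercept
  3 for NO₂) of the area-interpolated unit truth, modulated by a
  normalised seasonal-plus-episode daily factor plus noise. With zero
  noise the cell's annual mean is exactly `slope·truth + intercept`, the
  recovery target of the scaling tests.

Everything is seeded; hourly series are generated on demand with per-key
seeds derived from the master seed, so regeneration is bit-identical
regardless of access order, and a decade of hourly data never needs to be
held in memory at once.

What the generator does **not** emulate: atmospheric chemistry and
meteorology, spatially correlated episode timing between stations and
reanalysis, irregular unit geometry, reporting-format quirks of real
archives, and reanalysis unit conversion (all synthetic concentrations
are generated directly in µg m⁻³). Passing tests therefore demonstrate
the correctness of the *procedure* — metric arithmetic, selection logic,
zonal statistics, fit-and-apply machinery — not the real-data skill of
reanalysis-based gap filling, which depends on the actual correlation
between model and observations.

## Numerical choices and degenerate inputs

* Strict `>` for all thresholds; rounding is half-up (`floor(x + 0.5)`);
  counts are capped at the calendar maximum after scaling.
* Exact-recovery tests use a world whose 3° × 3° units are congruent with
  integer blocks of 0.75° cells, so cell-center clipping introduces no
  boundary mixing and the affine link is recovered to machine precision
  (< 10⁻⁶ relative). On the default, misaligned 402-unit world the same
  closure holds to < 1 % — the residual is exactly the boundary-mixing
  error of upscale-and-clip on county-sized units.
* Degenerate scaling inputs: < 3 pairs or zero predictor variance raise
  errors at the operation level; the pipeline-level fallback
  (intercept-only) is used only where the predictor carries no
  information at all.
* Boundary points in point-in-polygon and fine-cell membership are
  resolved deterministically (first code / half-open intervals) so
  repeated runs are byte-identical.

## Problem sizes used in the test-suite

The suite exercises the full 402-unit, ten-year configuration once
(≈ 12 000 records, about 5 000 station-year metric vectors, rasters of
12 × 11 cells × 2 920 timesteps per pollutant-year) and otherwise uses
12–20-unit worlds, which cover every code path at a fraction of the cost.
The metric oracle comparisons run on 50 full-year random series against a
loop-based reimplementation kept deliberately independent of the package
internals.

## Known limitations

* Scaling is global per metric × scenario: no spatially varying or
  uncertainty-propagating variant.
* Station averages are unweighted; data-capture weighting would be a
  plausible refinement.
* The cell-center clip is an approximation to exact area weighting,
  adequate at 0.01° for county-sized units but not for units comparable
  in size to a fine cell.
* A real-data adapter must resolve archive-specific issues the package
  deliberately leaves outside its scope: reanalysis unit conversion from
  mixing ratios, model-level selection, and archive CSV dialects.
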