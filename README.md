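# climspace

Holdridge life zones and the safe climatic space of food production.

## What this is for

Crop and livestock systems are tuned to the climates they grew up in. When
a grid cell's future climate moves into conditions under which essentially
no production exists today, past experience there stops being a guide. This
package provides the full gridded pipeline to quantify that risk for anyone
working with monthly climate rasters, gridded production data and a
societal-resilience layer: agro-climatologists, food-system risk modellers,
and anyone who needs Holdridge life zone maps under future scenarios.

## The method in brief

A 12-month climatology reduces to three linked Holdridge variables:
annual precipitation *P* (mm/yr), biotemperature
*T*<sub>bio</sub> = (1/12) Σ<sub>m</sub> max(*T*<sub>m</sub>, 0) (no upper
cap), and the PET ratio *R* = PET / *P* with PET = 58.93 · *T*<sub>bio</sub>.
These place each cell in the Holdridge triangle via

    P' = (log2 P − log2 62.5) / 8        R' = (log2 R − log2 0.125) / 8
    X  = 0.5 (1 + P' − R')               Y  = 1 − P' − R'

Cells are classified to the nearest of the 38 base-zone hexagon centroids
(frost splitting warm temperate from subtropical), aggregated to 13
classes. Climatic change is the (X, Y) displacement between baseline and
future, in units of the centroid spacing *d*<sub>0</sub> = 0.125, with a
dominant-driver direction (warmer/cooler, wetter/drier, more/less arid).
Change and resilience are cut into area-weighted quartiles and crossed into
a 16-class production risk table with critical/high risk zones. The **safe
climatic space** (SCS) of a sector is the set of triangle bins holding 95%
of baseline production mass; the share of production whose future climate
leaves it is computed per GCM and summarized by the ensemble median and
5th–95th percentile range, with GCM-agreement likelihood classes
(0 / 1–3 / 4–6 / 7–8 of 8 models) and country aggregation.

A seeded synthetic generator emulates all inputs (climate with latitudinal
gradient and seasonality, perturbed GCM futures, concentrated production,
smooth resilience, countries) with known ground truth, so the whole
pipeline is testable without external downloads. Real runs ingest regular
lat–lon rasters via plain-text ASCII grids.

## A worked example

```r
library(climspace)
spec <- scenario_spec(seed = 1)          # 90x180 grid, 8 GCMs, +2.4..4.8 C
clim <- generate_climate(spec)
ind  <- climate_indicators(clim$baseline)
prod <- generate_production(2, ind)
data <- list(baseline = clim$baseline, futures = clim$futures,
             production = prod,
             resilience = generate_resilience(3, clim$grid),
             countries  = generate_countries(4, clim$grid))
res <- run_pipeline(data)

res$risk
#> <risk_table> production shares (%), rows = change, cols = resilience
#> crop:
#>            resilience
#> change       low moderate high very high
#>   low        0.9      0.3  0.4       1.3
#>   moderate  11.6      6.9  3.9       3.2
#>   high       9.7     29.2 32.0       0.4
#>   very high  0.0      0.0  0.0       0.0
#> ...
#> critical risk: crop 0.0%, livestock 1.3%

res$scs$crop$share
#> <scs_share> median 21.1% outside SCS (5th-95th pct across 8 GCMs: 17.6-25.1%)
res$scs$livestock$share
#> <scs_share> median 10.1% outside SCS (5th-95th pct across 8 GCMs: 5.7-17.5%)

res$scs$crop$mask
#> <scs_mask> crop: 47 member bins (60 x 60), coverage target 0.95, inside 0.9513
```

Reading: under this synthetic high-warming ensemble, a median 21% of crop
production (18–25% across the 8 members) and 10% of livestock production
sit in future climates outside the bins holding 95% of today's production
mass. The 16-class table shows where production mass falls when change and
resilience quartiles are crossed; no crop mass lands in the very-high
change quartile here because this synthetic world's cropland sits where
change is moderate. `zone_areas(res$zones$baseline, res$areas)` tabulates
km² per life zone, and `plot_scs(res$scs$crop$mask)` draws the SCS in the
triangle.

A thin CLI wrapping the same functions ships in `inst/cli/scs.R`
(`Rscript inst/cli/scs.R run-all --seed 1 --out out/`).

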