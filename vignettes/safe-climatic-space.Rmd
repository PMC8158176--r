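---
title: "Holdridge life zones and the safe climatic space of food production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holdridge life zones and the safe climatic space of food production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climspace)
```

## The model

Agricultural systems are adapted to the climatic conditions under which they
developed. This package quantifies how far climate change pushes gridded
climate away from those conditions, using the Holdridge life zone (HLZ)
system, and how much crop and livestock production ends up in climates where
essentially no production exists today -- outside its *safe climatic space*
(SCS).

The HLZ system reduces a 12-month climatology to three linked variables:

* **Annual precipitation** `P` (mm/yr): the sum of the monthly totals.
* **Biotemperature** `Tbio` (deg C): the annual mean of monthly mean
  temperatures with sub-zero months contributing zero. We keep the
  zero-substitution convention -- sub-zero months enter as 0 and the divisor
  stays 12 -- because dropping those months from the divisor would inflate
  biotemperature toward the poles, where it should approach zero. We apply
  **no upper cap**: the classical variant also truncates months above 30 deg C,
  but an uncapped biotemperature gives a much more realistic potential
  evapotranspiration in hot, dry regions, so hot months enter at face value.
* **PET ratio** `R` (aridity, dimensionless): annual potential
  evapotranspiration over precipitation, with `PET = 58.93 * Tbio` mm/yr.
  `R > 1` means atmospheric demand exceeds supply.

Monthly mean temperature is estimated as the min/max midpoint
`(tmin + tmax)/2`. Where a baseline supplies true monthly means alongside
min/max, `baseline_offset()` computes the additive bias
`delta = mean - midpoint` per cell and month, and the same offset corrects
every future midpoint. An additive offset is the simplest correction
consistent with having exactly the baseline mean, min and max at hand; it is
an assumption, and it is switchable by passing `delta = 0`.

### The triangle

The HLZ chart is a triangle with logarithmic axes. Both axes span exactly
8 octaves -- precipitation 62.5 to 16,000 mm, PET ratio 0.125 to 32, each a
factor of 256 -- so the normalized coordinates are

    P' = (log2 P - log2 62.5) / 8
    R' = (log2 R - log2 0.125) / 8
    X  = 0.5 * (1 + P' - R')
    Y  = 1 - P' - R'

with `P', R'` in [0, 1]. The divisor is the constant 8 (the log2 of the
axis span): any position-dependent denominator would fail to map the axis
ranges onto [0, 1], which the Cartesian construction requires. Values beyond
the axis bounds -- including `P = 0` (hyper-arid) and `R = 0` (fully frozen,
`Tbio = 0`) -- are clamped to the bounds rather than dropped, so deserts and
polar cells stay classifiable; negative or non-finite inputs become no-data.

Because `log2 Tbio = log2 P + log2 R - log2 58.93`, lines of constant
`Y` are lines of constant biotemperature, and biotemperature doubles per
chart row. The 38 base zones sit on the half-integer log2 lattice
(`hlz_zones()`): 8 tropical, 7 + 7 in the 12--24 C row (split by the frost
line into subtropical and warm temperate), 6 cool temperate, 5 boreal,
4 subpolar, and a single polar desert merging the six lattice cells above
the 1.5 C line. Classification is nearest-centroid in `(X, Y)` with ties to
the lower zone id; the chart gives no explicit boundary rule, and
nearest-centroid reproduces its hexagonal geometry. A packaged, editable
table (`extdata/hlz_aggregation.csv`) merges the 38 base zones into 13
aggregated classes in the style of Leemans' aggregation, additionally
merging the two dry-side tropical forest classes; the exact naming of the
13 classes is partially an assumption, but includes every zone name used in
practice (tundra, boreal desert/forest, temperate desert/forest, tropical
desert, tropical dry forest, ...).

### Change metrics

Change between a baseline and a future position is the Euclidean `(X, Y)`
distance divided by `d0 = 0.125`, the spacing between adjacent same-row
hexagon centroids (one octave up one axis and down the other at fixed
biotemperature). The Cartesian rendering is not a perfectly regular
hexagonal lattice, so "the distance between two centroids" is not unique;
the within-row spacing is the unique constant spacing in this coordinate
system and is the normalization adopted. A change of 1 therefore moves a
cell from the center of one zone to the center of its neighbor.

The direction of change reduces to a dominant driver: components
`cP = dP'`, `cR = dR'` and `cT = cP + cR` (biotemperature, by the identity
above), with the largest absolute component winning and ties broken in the
order T, R, P. `change_vector()` exposes the raw displacement and angle.

Across a GCM ensemble the change map uses the cell-wise **median of the
derived variables** (P and Tbio; PET and R re-derived) before triangle
placement, with a majority vote for the frost flag. Whether the median
should be taken over climate variables, coordinates, or final change values
is underdetermined; medianing the physical variables keeps the derived
indicators mutually consistent and is the convention here. Per-GCM triangle
placement is retained wherever ensemble spread matters (the SCS layer).

### Risk classes

Change magnitudes and the resilience field (an external composite in
[-1, 1]) are each cut into quartile classes -- low, moderate, high, very
high -- at **area-weighted** 25/50/75th percentiles: each cell weighs its
geodesic area (`cell_areas()`, the spherical-band formula). The threshold is
the smallest field value at which the weighted cumulative distribution
reaches the target probability, and intervals are closed on the right at
each threshold, so a constant field is entirely "low". Passing a previously
derived `quantile_scheme` reuses its thresholds verbatim -- this is how a
high-emissions scenario is classified against thresholds derived from the
low-emissions reference so the two maps are comparable.

Production (crop kcal; livestock in animal units via the fixed
head-to-AU coefficients) is summed over the 16 change-by-resilience
combinations. Risk zones: *critical* = low resilience with very high
change; *high* = moderate resilience with very high change, or low
resilience with high change. The zones are mutually exclusive (critical
takes precedence), and both the separate and combined shares are reported
since published totals sometimes merge them. `resilience_sensitivity()`
re-runs the critical tabulation with the low-resilience cut at the 20th
through 30th percentiles.

### The safe climatic space

For each sector, baseline production mass is binned over `(X, Y)` --
regular rectangular bins, default 60 x 60 over the triangle's bounding box
-- and the smallest-mass bins are removed until just under 5% of the mass is
excluded. The retained bins are the SCS: they hold at least 95% of the mass,
minimally (dropping the smallest retained bin would go below target). The
bin resolution is a configuration knob; 60 x 60 is validated by the
parameter-recovery tolerance below.

A cell leaves the SCS under a GCM when its future position falls in a
non-member bin. The share of production outside is computed per GCM and
summarized by the median and the 5th--95th percentile range. The
denominator is, by default, the "major production areas": cells whose
baseline position is inside the mask, i.e. excluding the 5% filtered mass.
A `denominator = "all_production"` variant includes every production cell;
with a fixed denominator the outside share is provably nonincreasing in the
coverage target, while the default's denominator itself depends on the
mask. The analogous 5% filter on *future* conditions is applied only to
density visualization, not to the outside-share statistic, which would
otherwise be non-conservative.

GCM agreement is mapped with the 8-member bins 0 / 1--3 / 4--6 / 7--8
(very likely inside / likely inside / potentially outside / likely
outside), and aggregated per country together with a "no or minor
production" share for the filtered 5%.

## Synthetic data and what it does (not) show

`generate_climate()` builds a deterministic climatology -- an equator-to-pole
annual-mean gradient (27 deg C down to about -18 deg C at 85 deg), a
hemisphere-phased seasonal cycle growing with latitude, a wet-tropics /
dry-subtropics / moist-mid-latitude precipitation profile with mild
longitudinal structure -- plus seeded heterogeneity: Gaussian noise added
jointly to tmin and tmax (preserving their order) and multiplicative
lognormal noise on precipitation (preserving positivity). Future members
add a per-GCM warming offset and precipitation multiplier plus fresh noise.
The defaults are an 8-member ensemble with warming offsets spread over
2.4--4.8 deg C and precipitation multipliers over 0.9--1.1, i.e. an
end-of-century high-emissions-like spread; the default grid is 90 x 180
cells spanning 85 S--85 N, a coarse analogue of a 5 arc-min global grid that
still exercises area weighting. Production concentrates where suitability
(mid-range biotemperature and precipitation) is high, raised to a
concentration exponent; resilience is a smooth seeded harmonic field through
`tanh`; countries are a Voronoi partition.

The generator emulates the *structure* of real inputs -- gradients,
seasonality, ensemble spread, concentrated production -- not the spatial
covariance of real GCM fields, coastlines, orography, or downscaling
artifacts. Passing tests therefore demonstrate that the machinery is
correct (classification geometry, weighting, mass accounting, ensemble
logic), not that any particular real-world number is reproduced; real runs
require the external climate, production and resilience rasters.

`make_known_outside_scenario(f)` is the ground-truth oracle: it displaces
the future climate of a production subset carrying fraction `f` of total
mass to the frozen apex of the chart (precipitation at the axis lower
bound, biotemperature zero), far outside any plausible SCS, leaving all
other futures identical to the baseline. The subset is drawn stratified by
baseline SCS membership -- fraction `f` of the mass inside the mask and
`f` of the mass outside it -- so the displaced mass is `f` of the total
*and* the outside-share statistic, whose denominator excludes the filtered
5%, recovers `f`. Selection is greedy by descending cell mass, so each
stratum lands within one cell's mass of its target. Recovery across
`f = 0, 0.1, ..., 1` is within 0.02 at the default binning (exact at 0
and 1), which is the validation behind the default 60 x 60 bins.

## Numerical choices and degenerate inputs

* Weighted-percentile convention as above; it matches a brute-force
  weighted-cumulative-sort oracle exactly.
* Nearest-centroid ties go to the lowest zone id; equidistant points are
  vanishingly rare on real data but the rule is deterministic.
* `P = 0` maps to `R = 32` (desert corner); `R = 0` clamps to 0.125
  (polar corner); negative or non-finite inputs are no-data, and any
  missing month poisons all indicators for that cell.
* A constant field classifies entirely "low"; an all-no-data field is
  rejected, as are misaligned grids (no silent resampling anywhere) and
  all-zero production.
* Even-count ensemble medians average the two middle order statistics.
* `frost_free` is strict: a month at exactly 0 deg C counts as frost.

## Problem sizes

Tests run on 30 x 60 (units) and 90 x 180 grids (end-to-end properties and
the recovery sweep); the full default pipeline -- 8 GCMs, 90 x 180, 12
months -- runs in a few seconds, and the complete recovery sweep in well
under a minute. These sizes were chosen so the whole suite iterates
comfortably on a laptop while still spanning multiple biotemperature rows,
both hemispheres and a nontrivial SCS.

## Known limitations

* No raster-format interoperability with binary geospatial formats;
  I/O uses plain-text ASCII grids, per-month stacks and CSV tables. The
  alignment contract (shared grid, explicit refusal to resample) is
  enforced at read time.
* Stage outputs are not cached between runs; the pipeline is cheap enough
  at desk scale that reruns recompute everything deterministically.
* The 13-class legend naming, the additive bias correction, and the
  ensemble-median convention are documented assumptions where the
  underlying chart or text is silent.
* Country aggregation reports both sectors separately; there is no single
  "food production" composite.

## A short run

```{r example, eval = FALSE}
spec <- scenario_spec(seed = 1)
clim <- generate_climate(spec)
ind  <- climate_indicators(clim$baseline)
prod <- generate_production(2, ind)

data <- list(baseline = clim$baseline, futures = clim$futures,
             production = prod,
             resilience = generate_resilience(3, clim$grid),
             countries  = generate_countries(4, clim$grid))
res <- run_pipeline(data)

res$risk                           # 16-class production shares
res$scs$crop$share                 # per-GCM outside-SCS shares
zone_areas(res$zones$baseline, res$areas)
plot_scs(res$scs$crop$mask)
```
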