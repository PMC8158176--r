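# Small shared fixtures. Desk-scale grids keep each file in seconds; the
# acceptance tests use the full default 90 x 180 grid where the property
# being checked depends on it.

small_spec <- function(seed = 42, ...) {
  scenario_spec(nlat = 30L, nlon = 60L, seed = seed, n_gcm = 3L, ...)
}

# A complete small synthetic dataset (baseline + futures + production +
# resilience + countries), memoised per seed within a test run.
small_dataset <- local({
  cache <- list()
  function(seed = 42) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      spec <- small_spec(seed)
      clim <- generate_climate(spec)
      ind <- climate_indicators(clim$baseline)
      cache[[key]] <<- list(
        spec = spec, grid = clim$grid,
        baseline = clim$baseline, futures = clim$futures,
        indicators = ind,
        production = generate_production(seed + 1L, ind),
        resilience = generate_resilience(seed + 2L, clim$grid),
        countries = generate_countries(seed + 3L, clim$grid))
    }
    cache[[key]]
  }
})

# Monthly climate built directly from per-cell vectors, for hand-constructed
# indicator cases: `values` is a list with prec/tmin/tmax 12-vectors applied
# to every cell of a tiny grid.
uniform_climate <- function(prec, tmin, tmax, nlat = 2, nlon = 2) {
  grid <- cs_grid(nlat, nlon, lat_max = 60)
  arr <- function(v) aperm(array(rep(v, each = nlat * nlon),
                                 c(nlat, nlon, 12)), c(1, 2, 3))
  monthly_climate(arr(prec), arr(tmin), arr(tmax), grid)
}
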