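# Seeded synthetic generator: determinism, physicality, perturbation
# contracts, and the known-outside ground-truth construction.

test_that("scenario specs validate their inputs", {
  expect_error(scenario_spec(nlat = 1), "at least 2 x 2")
  expect_error(scenario_spec(precip_mult = c(1, -0.5)), "> 0")
  expect_error(scenario_spec(temp_noise = -1), ">= 0")
  expect_s3_class(small_spec(), "scenario_spec")
})

test_that("identical specs give bit-identical climate; different seeds differ", {
  a <- generate_climate(small_spec(seed = 1))
  b <- generate_climate(small_spec(seed = 1))
  c <- generate_climate(small_spec(seed = 2))
  expect_identical(a$baseline$prec, b$baseline$prec)
  expect_identical(a$futures$gcm02$tmax, b$futures$gcm02$tmax)
  expect_false(identical(a$baseline$prec, c$baseline$prec))
})

test_that("generated climate is physical and latitudinally structured", {
  clim <- generate_climate(small_spec())
  for (cl in c(list(clim$baseline), clim$futures)) {
    expect_true(all(cl$prec >= 0))
    expect_true(all(cl$tmin <= cl$tmax))
  }
  # warmer at the equator than at the poles, on annual means
  tmean <- monthly_mean_temperature(clim$baseline$tmin, clim$baseline$tmax)
  ann <- rowMeans(matrix(tmean, nrow = dim(tmean)[1]))
  nlat <- length(ann)
  expect_gt(ann[nlat / 2], ann[1])
  expect_gt(ann[nlat / 2], ann[nlat])
  # seasonal cycle present away from the equator
  expect_gt(max(tmean[2, 1, ]) - min(tmean[2, 1, ]), 5)
})

test_that("future members apply exactly their warming offset and multiplier", {
  spec <- small_spec(seed = 3, warming = c(0, 4, 1), precip_mult = c(1, 1, 2),
                     temp_noise = 0, precip_noise = 0)
  clim <- generate_climate(spec)
  expect_equal(clim$futures[[1]]$tmin, clim$baseline$tmin)
  expect_equal(clim$futures[[1]]$prec, clim$baseline$prec)
  expect_equal(clim$futures[[2]]$tmin, clim$baseline$tmin + 4)
  expect_equal(clim$futures[[2]]$tmax, clim$baseline$tmax + 4)
  expect_equal(clim$futures[[3]]$prec, 2 * clim$baseline$prec)
})

test_that("production is nonnegative, concentrated, seeded and validated", {
  ds <- small_dataset()
  prod <- ds$production
  expect_true(all(prod$crop >= 0))
  expect_gt(sum(prod$crop), 0)
  expect_equal(prod$crop, generate_production(43, ds$indicators)$crop)
  # infinite concentration puts everything in one cell
  point <- generate_production(43, ds$indicators, concentration = Inf)
  expect_equal(sum(point$crop > 0), 1)
  expect_equal(sum(point$crop), 1e12)
  # AU field is reproduced by converting the species headcounts back
  expect_equal(to_animal_units(prod$livestock), prod$livestock_au)
})

test_that("resilience stays in [-1, 1], is smooth, and supports constants", {
  ds <- small_dataset()
  r <- ds$resilience
  expect_gte(min(r), -1)
  expect_lte(max(r), 1)
  # smoothness: neighbouring cells differ far less than the global range
  expect_lt(max(abs(diff(r))), diff(range(r)) / 4)
  expect_identical(r, generate_resilience(44, ds$grid))
  const <- generate_resilience(1, ds$grid, constant = 0.25)
  expect_true(all(const == 0.25))
  expect_error(generate_resilience(1, ds$grid, constant = 2))
})

test_that("known-outside scenarios displace the requested mass fraction", {
  spec <- small_spec(seed = 5)
  sc0 <- make_known_outside_scenario(0, spec)
  expect_length(sc0$truth$cells, 0)
  expect_equal(sc0$truth$fraction, 0)
  expect_identical(sc0$futures[[1]]$prec, sc0$baseline$prec)
  sc1 <- make_known_outside_scenario(1, spec)
  expect_equal(sc1$truth$fraction, 1)
  sc <- make_known_outside_scenario(0.3, spec)
  total <- sum(sc$production$crop)
  expect_equal(sum(sc$production$crop[sc$truth$cells]) / total,
               sc$truth$fraction)
  # within one cell's mass of the request
  expect_lt(abs(sc$truth$fraction - 0.3),
            2 * max(sc$production$crop) / total + 1e-12)
  expect_error(make_known_outside_scenario(1.2), "\\[0, 1\\]")
})
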