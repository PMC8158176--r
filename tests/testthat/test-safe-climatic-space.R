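# SCS construction (coverage and minimality), membership, outside shares,
# likelihood classes, and country aggregation.

test_that("SCS keeps >= coverage of mass and is minimal", {
  ds <- small_dataset()
  tri <- to_triangle(ds$indicators$P, ds$indicators$R)
  for (cov in c(0.8, 0.95, 0.99)) {
    mask <- build_scs(tri, ds$production$crop, coverage = cov)
    expect_gte(mask$inside_share, cov)
    # minimality: dropping the smallest retained bin goes below coverage
    retained <- mask$mass[mask$member]
    expect_lt(mask$inside_share - min(retained) / sum(mask$mass), cov)
  }
  expect_error(build_scs(tri, 0 * ds$production$crop), "zero total")
  expect_error(build_scs(tri, ds$production$crop, coverage = 1.2), "coverage")
})

test_that("two-bin cumulative-mass rule drops only the small bin", {
  # all mass in two bins, split 96/4: at coverage 0.95 only the large stays
  pts <- list(Pp = c(0.3, 0.7), Rp = c(0.3, 0.7),
              X = c(0.5, 0.5), Y = c(0.4, -0.4))
  class(pts) <- "triangle_points"
  mask <- build_scs(pts, c(96, 4), coverage = 0.95)
  expect_equal(sum(mask$member), 1)
  expect_equal(mask$inside_share, 0.96)
  expect_true(scs_contains(mask, list(X = 0.5, Y = 0.4)))
  expect_false(scs_contains(mask, list(X = 0.5, Y = -0.4)))
  # single-bin case: the mask is that bin
  one <- build_scs(list(X = 0.5, Y = 0), 10, coverage = 0.95)
  expect_equal(sum(one$member), 1)
})

test_that("future equal to baseline yields zero outside share", {
  ds <- small_dataset()
  tri <- to_triangle(ds$indicators$P, ds$indicators$R)
  mask <- build_scs(tri, ds$production$crop)
  sh <- outside_scs_share(list(tri, tri), tri, ds$production$crop, mask)
  expect_equal(unname(sh$per_gcm), c(0, 0))
  expect_equal(sh$median, 0)
})

test_that("displacing everything beyond the axis bounds gives share 1", {
  ds <- small_dataset()
  tri <- to_triangle(ds$indicators$P, ds$indicators$R)
  mask <- build_scs(tri, ds$production$crop)
  far <- to_triangle(matrix(62.5, nrow(ds$indicators$P), ncol(ds$indicators$P)),
                     matrix(0.125, nrow(ds$indicators$P), ncol(ds$indicators$P)))
  sh <- outside_scs_share(list(far), tri, ds$production$crop, mask)
  expect_equal(unname(sh$per_gcm), 1)
})

test_that("outside share recovers constructed ground-truth fractions", {
  for (f in c(0, 0.25, 0.5, 1)) {
    sc <- make_known_outside_scenario(f, small_spec(seed = 6))
    ind <- climate_indicators(sc$baseline)
    base_tri <- to_triangle(ind$P, ind$R)
    fut_tri <- lapply(sc$futures, function(cl) {
      i <- climate_indicators(cl)
      to_triangle(i$P, i$R)
    })
    sh <- outside_scs_share(fut_tri, base_tri, sc$production$crop, sc$mask)
    expect_equal(sh$median, f, tolerance = if (f %in% c(0, 1)) 1e-12 else 0.02)
  }
})

test_that("outside share is nonincreasing in coverage", {
  sc <- make_known_outside_scenario(0.4, small_spec(seed = 8))
  ind <- climate_indicators(sc$baseline)
  base_tri <- to_triangle(ind$P, ind$R)
  fut <- climate_indicators(sc$futures[[1]])
  fut_tri <- to_triangle(fut$P, fut$R)
  # with a fixed denominator (every production cell) a larger SCS can only
  # shrink the outside share
  shares <- vapply(c(0.7, 0.8, 0.9, 0.95, 0.99), function(cov) {
    mask <- build_scs(base_tri, sc$production$crop, coverage = cov)
    outside_scs_share(list(fut_tri), base_tri, sc$production$crop,
                      mask, denominator = "all_production")$median
  }, numeric(1))
  expect_true(all(diff(shares) <= 1e-9))
})

test_that("likelihood classes follow the 0 / 1-3 / 4-6 / 7-8 agreement bins", {
  # one-cell fields covering every count 0..8
  for (k in 0:8) {
    fields <- lapply(seq_len(8), function(g) matrix(g <= k, 1, 1))
    lk <- likelihood_map(fields)
    expect_equal(lk$count[1, 1], k)
    expected <- if (k == 0) 1L else if (k <= 3) 2L else if (k <= 6) 3L else 4L
    expect_equal(unclass(lk$category)[1, 1], expected)
  }
  # permutation invariance
  set.seed(31)
  fields <- lapply(1:8, function(g) matrix(runif(12) < 0.5, 3, 4))
  expect_equal(likelihood_map(fields)$count,
               likelihood_map(rev(fields))$count)
  expect_error(likelihood_map(fields, n_gcm = 6), "expected")
})

test_that("country aggregation recovers global totals and splits", {
  ds <- small_dataset()
  tri <- to_triangle(ds$indicators$P, ds$indicators$R)
  mask <- build_scs(tri, ds$production$crop)
  far <- to_triangle(0 * ds$indicators$P + 62.5, 0 * ds$indicators$R + 0.125)
  sh <- outside_scs_share(list(far, tri, tri), tri, ds$production$crop, mask)
  # single country: rows equal the global decomposition
  one <- country_aggregate(sh, ds$production$crop, NULL, sector = "crop")
  expect_equal(nrow(one), 1)
  expect_equal(sum(as.numeric(one[1, 4:7])) + one$no_or_minor, 100,
               tolerance = 1e-9)
  # constructed 2-country split: all outside mass in country 1
  countries <- matrix(2L, nrow(tri$X), ncol(tri$X))
  countries[1:10, ] <- 1L
  out1 <- sh$outside[[1]] & countries == 1L
  sh2 <- sh
  sh2$outside <- lapply(sh$outside, function(o) o & countries == 1L)
  tab <- country_aggregate(sh2, ds$production$crop, countries)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$outside_share[tab$country == 2], 0)
  # per-country category + minor shares always sum to 100
  sums <- rowSums(tab[, 4:7]) + tab$no_or_minor
  expect_equal(unname(sums), rep(100, 2), tolerance = 1e-9)
})
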