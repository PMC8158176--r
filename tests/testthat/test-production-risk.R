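# Animal units, cell areas, area-weighted quantile classes, the 16-class
# production crosstab, risk-zone labels, and the resilience sensitivity scan.

test_that("animal-unit conversion applies the species coefficients linearly", {
  expect_equal(to_animal_units(list(buffalo = 1)), 0.7)
  expect_equal(to_animal_units(list(chickens = 100)), 1)
  expect_equal(to_animal_units(list(cattle = matrix(0, 2, 2)))[1, 1], 0)
  expect_error(to_animal_units(list(llamas = 5)), "unknown")
  set.seed(5)
  a <- list(cattle = matrix(runif(4), 2), sheep = matrix(runif(4), 2))
  b <- list(cattle = matrix(runif(4), 2), sheep = matrix(runif(4), 2))
  ab <- list(cattle = a$cattle + b$cattle, sheep = a$sheep + b$sheep)
  expect_equal(to_animal_units(ab), to_animal_units(a) + to_animal_units(b))
})

test_that("cell areas follow the cosine-latitude law and sum to Earth's surface", {
  g <- cs_grid(90, 180, lat_max = 90)
  a <- cell_areas(g)
  # hemispheric symmetry: row i mirrors row nlat + 1 - i
  expect_equal(a, a[rev(seq_len(nrow(a))), ])
  direct <- cell_areas(c(0, 40, -40, 60), dlat = 0.5, dlon = 0.5)
  expect_equal(direct[2, 1], direct[3, 1])
  expect_equal(direct[4, 1] / direct[1, 1], cos(60 * pi / 180),
               tolerance = 1e-4)
  expect_equal(sum(a), 5.10e8, tolerance = 0.005)
  expect_error(cell_areas(c(80, 95), dlat = 1, dlon = 1), "latitudes")
})

test_that("area-weighted quantile thresholds match a cumulative-sort oracle", {
  set.seed(17)
  for (k in 1:5) {
    n <- 500
    x <- rnorm(n)
    w <- runif(n, 0.5, 2)
    thr <- weighted_quantile(x, w, c(0.25, 0.5, 0.75))
    ord <- order(x)
    cw <- cumsum(w[ord]) / sum(w)
    oracle <- vapply(c(0.25, 0.5, 0.75),
                     function(p) x[ord][min(which(cw >= p))], numeric(1))
    expect_identical(thr, oracle)
  }
  # equal weights, values 1..100: thresholds at the 25/50/75th elements
  expect_equal(weighted_quantile(1:100, rep(1, 100), c(0.25, 0.5, 0.75)),
               c(25, 50, 75))
})

test_that("quantile classes cover ~25% of area each and reuse supplied schemes", {
  ds <- small_dataset()
  areas <- cell_areas(ds$grid)
  field <- matrix(rnorm(length(areas)), nrow(areas))
  qc <- quantile_classes(field, areas)
  tot <- sum(areas)
  max_cell <- max(areas) / tot
  for (k in 1:4)
    expect_lt(abs(sum(areas[qc$classes == k]) / tot - 0.25), 2 * max_cell)
  # reuse rule: classifying 2x the field against the original thresholds
  qc2 <- quantile_classes(2 * field, areas, scheme = qc$scheme)
  expect_identical(qc2$scheme$thresholds, qc$scheme$thresholds)
  recomputed <- 1L + (2 * field > qc$scheme$thresholds[1]) +
    (2 * field > qc$scheme$thresholds[2]) +
    (2 * field > qc$scheme$thresholds[3])
  expect_equal(unclass(qc2$classes), recomputed, ignore_attr = TRUE)
  # degenerate constant field: everything "low"
  const <- quantile_classes(matrix(1, 4, 4), matrix(1, 4, 4))
  expect_true(all(const$classes == 1L))
  expect_error(quantile_classes(matrix(NA_real_, 2, 2), matrix(1, 2, 2)))
})

test_that("risk-zone labels implement the critical/high definitions", {
  expect_equal(risk_zone_labels("very high", "low"), "critical")
  expect_equal(risk_zone_labels("very high", "moderate"), "high")
  expect_equal(risk_zone_labels("high", "low"), "high")
  expect_equal(risk_zone_labels("low", "very high"), "other")
  expect_error(risk_zone_labels("extreme", "low"), "unknown")
  m <- risk_zone_matrix()
  expect_equal(sum(m$risk_zone == "critical"), 1)
  expect_equal(sum(m$risk_zone == "high"), 2)
  # mutually exclusive: the critical cell is not also high
  expect_false(any(m$risk_zone == "critical" & m$risk_zone == "high"))
})

test_that("crosstab shares sum to 100 and concentrate where production does", {
  ch <- matrix(rep(1:4, each = 4), 4, 4)
  re <- matrix(rep(1:4, times = 4), 4, 4)
  one <- matrix(0, 4, 4); one[2, 3] <- 5
  rt <- risk_crosstab(ch, re, one, one)
  expect_equal(sum(rt$crop), 100)
  expect_equal(rt$crop[ch[2, 3], re[2, 3]], 100)
  # full-spread grid populates all 16 classes
  full <- matrix(1, 4, 4)
  rt2 <- risk_crosstab(ch, re, full, full)
  expect_equal(sum(rt2$crop > 0), 16)
  expect_equal(sum(rt2$livestock), 100, tolerance = 1e-6)
  expect_error(risk_crosstab(ch, re, one[1:2, ], one), "misaligned")
})

test_that("crosstab marginals equal independently computed class shares", {
  ds <- small_dataset()
  areas <- cell_areas(ds$grid)
  set.seed(23)
  ch <- quantile_classes(matrix(rnorm(length(areas)), nrow(areas)), areas)
  re <- quantile_classes(ds$resilience, areas)
  crop <- ds$production$crop
  au <- ds$production$livestock_au
  rt <- risk_crosstab(ch$classes, re$classes, crop, au)
  marg <- rowSums(rt$crop)
  for (k in 1:4)
    expect_equal(marg[k], 100 * sum(crop[ch$classes == k]) / sum(crop),
                 ignore_attr = TRUE)
})

test_that("resilience sensitivity is consistent at 25 and monotone in percentile", {
  ds <- small_dataset()
  areas <- cell_areas(ds$grid)
  set.seed(29)
  ch <- quantile_classes(matrix(rnorm(length(areas)), nrow(areas)), areas)
  crop <- ds$production$crop
  au <- ds$production$livestock_au
  sens <- resilience_sensitivity(ch$classes, ds$resilience, areas, crop, au,
                                 percentiles = 20:30)
  expect_equal(nrow(sens), 11)
  # shares nondecreasing as the low-resilience set grows
  expect_true(all(diff(sens$crop_share) >= -1e-12))
  expect_true(all(diff(sens$livestock_share) >= -1e-12))
  # the 25th-percentile row equals the default crosstab critical share
  re <- quantile_classes(ds$resilience, areas)
  rt <- risk_crosstab(ch$classes, re$classes, crop, au)
  expect_equal(sens$crop_share[sens$percentile == 25],
               unname(rt$crop_risk["critical"]), tolerance = 1e-10)
  expect_error(resilience_sensitivity(ch$classes, ds$resilience, areas,
                                      crop, au, percentiles = numeric(0)))
  one <- resilience_sensitivity(ch$classes, ds$resilience, areas, crop, au,
                                percentiles = 25)
  expect_equal(nrow(one), 1)
})
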