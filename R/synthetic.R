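# Seeded synthetic inputs: monthly climate with a latitudinal gradient and
# seasonal cycle, per-GCM perturbed futures, spatially concentrated crop and
# livestock production, a smooth resilience field, a country raster, and a
# constructed scenario with a known production fraction displaced outside
# the safe climatic space.

#' Specification of a synthetic climate scenario
#'
#' Grid geometry, seeding and per-GCM perturbations for the synthetic
#' generator. Defaults emulate a coarse desk-scale analogue of a 5 arc-min
#' global run: a 90 x 180 grid spanning 85 S--85 N, an 8-member ensemble
#' with end-of-century warming offsets spread over 2.4--4.8 C and
#' precipitation multipliers over 0.9--1.1.
#'
#' @param nlat,nlon grid shape (each >= 2).
#' @param lat_max latitude extent in degrees.
#' @param seed integer seed; the same spec yields bit-identical rasters.
#' @param n_gcm ensemble size.
#' @param warming per-GCM additive offset (deg C) applied to monthly
#'   tmin/tmax; recycled/validated to length `n_gcm`.
#' @param precip_mult per-GCM multiplicative precipitation factor (> 0).
#' @param temp_noise s.d. (deg C) of the seeded per-cell-month temperature
#'   noise (applied to tmin and tmax jointly, preserving tmin <= tmax).
#' @param precip_noise s.d. of the multiplicative lognormal precipitation
#'   noise (fraction of precipitation; keeps precipitation positive).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(nlat = 90L, nlon = 180L, lat_max = 85, seed = 1L,
                          n_gcm = 8L,
                          warming = seq(2.4, 4.8, length.out = n_gcm),
                          precip_mult = seq(0.9, 1.1, length.out = n_gcm),
                          temp_noise = 0.4, precip_noise = 0.08) {
  if (nlat < 2 || nlon < 2) stop("grid must be at least 2 x 2")
  if (n_gcm < 1) stop("need at least one GCM")
  warming <- rep_len(warming, n_gcm)
  precip_mult <- rep_len(precip_mult, n_gcm)
  if (any(precip_mult <= 0)) stop("precipitation multipliers must be > 0")
  if (temp_noise < 0 || precip_noise < 0) stop("noise scales must be >= 0")
  structure(list(nlat = as.integer(nlat), nlon = as.integer(nlon),
                 lat_max = lat_max, seed = as.integer(seed),
                 n_gcm = as.integer(n_gcm), warming = warming,
                 precip_mult = precip_mult, temp_noise = temp_noise,
                 precip_noise = precip_noise),
            class = "scenario_spec")
}

# Deterministic baseline climatology: zonal temperature gradient with a
# hemisphere-phased seasonal cycle, a wet tropics / dry subtropics / moist
# mid-latitude precipitation profile, and mild longitudinal structure so the
# fields are genuinely two-dimensional.
.baseline_pattern <- function(grid) {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  L <- matrix(grid$lat, nlat, nlon)
  Lo <- matrix(grid$lon, nlat, nlon, byrow = TRUE)
  tmean_ann <- 27 - 45 * (abs(L) / 85)^1.6 +
    2 * sin(3 * 2 * pi * Lo / 360 + L / 25)
  amp <- 1 + 14 * (abs(L) / 85)^1.3           # seasonal amplitude, deg C
  diurnal <- 8 + 4 * abs(L) / 85              # tmax - tmin, deg C
  p_ann <- 2200 * exp(-(L / 14)^2) +
    900 * exp(-((abs(L) - 50) / 16)^2) + 150  # mm/yr, zonal profile
  p_ann <- p_ann * pmax(1 + 0.4 * sin(2 * 2 * pi * Lo / 360 + L / 30), 0.2)
  seas <- function(m) cos(2 * pi * (m - 7) / 12)   # +1 in July
  prec <- tmin <- tmax <- array(0, c(nlat, nlon, 12))
  for (m in 1:12) {
    tm <- tmean_ann + sign(L) * amp * seas(m)
    tmin[, , m] <- tm - diurnal / 2
    tmax[, , m] <- tm + diurnal / 2
    wet <- pmax(1 + 0.6 * sign(L) * seas(m), 0.05)  # wet summers
    prec[, , m] <- p_ann * wet / 12
  }
  # renormalize monthly shares so the annual total equals p_ann exactly
  tot <- annual_precipitation(prec)
  for (m in 1:12) prec[, , m] <- prec[, , m] * ifelse(tot > 0, p_ann / tot, 0)
  list(prec = prec, tmin = tmin, tmax = tmax)
}

#' Generate seeded synthetic baseline and per-GCM future climate
#'
#' The baseline combines the deterministic climatology with seeded
#' cell-and-month heterogeneity (Gaussian for temperature, multiplicative
#' lognormal for precipitation). Each future member is the baseline plus its
#' GCM's warming offset on tmin/tmax, times its precipitation multiplier,
#' plus fresh seeded noise at the same scales; with zero offsets,
#' unit multipliers and zero noise the futures are identical to the
#' baseline.
#'
#' @param spec a [scenario_spec()].
#' @return List with `grid`, `baseline` (a [monthly_climate()]) and
#'   `futures` (named list of `n_gcm` [monthly_climate()] objects).
#' @export
generate_climate <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  grid <- cs_grid(spec$nlat, spec$nlon, spec$lat_max)
  set.seed(spec$seed)
  base <- .baseline_pattern(grid)
  n <- spec$nlat * spec$nlon * 12L
  eps <- array(stats::rnorm(n, 0, spec$temp_noise), dim(base$tmin))
  lnz <- array(stats::rnorm(n, 0, spec$precip_noise), dim(base$prec))
  baseline <- monthly_climate(
    prec = base$prec * exp(lnz - spec$precip_noise^2 / 2),
    tmin = base$tmin + eps, tmax = base$tmax + eps, grid = grid,
    period = "1970-2000", scenario = "historical", gcm = "none")
  futures <- vector("list", spec$n_gcm)
  names(futures) <- sprintf("gcm%02d", seq_len(spec$n_gcm))
  for (g in seq_len(spec$n_gcm)) {
    eg <- array(stats::rnorm(n, 0, spec$temp_noise), dim(base$tmin))
    zg <- array(stats::rnorm(n, 0, spec$precip_noise), dim(base$prec))
    futures[[g]] <- monthly_climate(
      prec = baseline$prec * spec$precip_mult[g] *
        exp(zg - spec$precip_noise^2 / 2),
      tmin = baseline$tmin + spec$warming[g] + eg,
      tmax = baseline$tmax + spec$warming[g] + eg, grid = grid,
      period = "2081-2100", scenario = "future", gcm = names(futures)[g])
  }
  list(grid = grid, baseline = baseline, futures = futures)
}

#' Generate synthetic crop and livestock production
#'
#' Places production where the climate is suitable: a smooth suitability
#' surface peaking at mid-range biotemperature and precipitation, raised to
#' the `concentration` power (larger = more spatially concentrated;
#' `Inf` puts all mass in the single most suitable cell), times seeded
#' lognormal heterogeneity. Livestock uses a broader suitability surface and
#' is split into the seven species by a fixed animal-unit mix.
#'
#' @param seed integer seed.
#' @param indicators baseline [climate_indicators()].
#' @param concentration nonnegative concentration exponent (default 4).
#' @param crop_total total crop production (kcal) to distribute.
#' @param livestock_total total livestock mass (AU) to distribute.
#' @return List with `crop` (kcal matrix), `livestock_au` (AU matrix) and
#'   `livestock` (named list of seven headcount matrices whose AU sum
#'   reproduces `livestock_au`).
#' @export
generate_production <- function(seed, indicators, concentration = 4,
                                crop_total = 1e12, livestock_total = 1e9) {
  stopifnot(inherits(indicators, "climate_indicators"))
  if (concentration < 0) stop("concentration must be >= 0")
  set.seed(seed)
  Tb <- indicators$Tbio; P <- indicators$P
  suit <- function(t0, ts, p0, ps)
    exp(-((Tb - t0) / ts)^2 - ((log2(pmax(P, 1)) - log2(p0)) / ps)^2)
  shape <- function(s, conc, total) {
    noise <- matrix(exp(stats::rnorm(length(s), 0, 0.5)), nrow(s), ncol(s))
    if (is.infinite(conc)) {
      out <- matrix(0, nrow(s), ncol(s))
      out[which.max(s * noise)] <- total
      return(out)
    }
    w <- s^conc * noise
    w[is.na(w)] <- 0
    w[w < max(w) * 1e-9] <- 0       # trim the far climatic tail
    if (sum(w) <= 0) stop("degenerate production field: all-zero output")
    total * w / sum(w)
  }
  crop <- shape(suit(18, 7, 900, 1.2), concentration, crop_total)
  au <- shape(suit(15, 10, 600, 1.8), max(1, concentration / 2),
              livestock_total)
  mix <- c(cattle = 0.45, sheep = 0.12, goats = 0.08, horses = 0.02,
           buffalo = 0.05, chickens = 0.18, pigs = 0.10)
  coefs <- animal_unit_coefficients()
  livestock <- lapply(names(mix), function(sp) au * mix[[sp]] / coefs[[sp]])
  names(livestock) <- names(mix)
  list(crop = crop, livestock_au = au, livestock = livestock)
}

#' Generate a smooth synthetic resilience field
#'
#' A seeded sum of low-frequency harmonics squashed through `tanh`, giving a
#' spatially smooth field strictly inside \[-1, 1\]; optionally a constant
#' field.
#'
#' @param seed integer seed.
#' @param grid a [cs_grid()].
#' @param constant if non-`NULL`, every cell takes this value (must lie in
#'   \[-1, 1\]).
#' @return Matrix in \[-1, 1\].
#' @export
generate_resilience <- function(seed, grid, constant = NULL) {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  if (!is.null(constant)) {
    if (abs(constant) > 1) stop("constant resilience must lie in [-1, 1]")
    return(matrix(constant, nlat, nlon))
  }
  set.seed(seed)
  L <- matrix(grid$lat, nlat, nlon) / 90
  Lo <- matrix(grid$lon, nlat, nlon, byrow = TRUE) / 180
  f <- matrix(0, nlat, nlon)
  for (k in 1:3) {
    a <- stats::rnorm(2, 0, 0.45)
    fx <- sample(1:2, 1)
    ph <- stats::runif(2, 0, 2 * pi)
    f <- f + a[1] * sin(pi * L + ph[1]) * cos(pi * fx * Lo + ph[2]) +
      a[2] * L / 3
  }
  tanh(f)
}

#' Generate a blocky synthetic country raster
#'
#' Nearest-seed (Voronoi) partition of the grid into `n_countries` contiguous
#' regions, with longitudinal wrap-around.
#'
#' @param seed integer seed.
#' @param grid a [cs_grid()].
#' @param n_countries number of regions.
#' @return Integer matrix of country ids 1..`n_countries`.
#' @export
generate_countries <- function(seed, grid, n_countries = 20L) {
  set.seed(seed)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  cl <- stats::runif(n_countries, min(grid$lat), max(grid$lat))
  cn <- stats::runif(n_countries, -180, 180)
  L <- matrix(grid$lat, nlat, nlon)
  Lo <- matrix(grid$lon, nlat, nlon, byrow = TRUE)
  best <- matrix(Inf, nlat, nlon)
  id <- matrix(1L, nlat, nlon)
  for (k in seq_len(n_countries)) {
    dlon <- abs(Lo - cn[k])
    dlon <- pmin(dlon, 360 - dlon)
    d2 <- (L - cl[k])^2 + (dlon * cos(L * pi / 180))^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    id[upd] <- k
  }
  id
}

# Greedy subset of cells (by descending mass) whose mass approaches
# `fraction` of the stratum total from below; the shortfall is smaller than
# the smallest unselected cell's mass.
.select_mass_fraction <- function(mass, cells, fraction) {
  if (fraction <= 0 || !length(cells)) return(integer(0))
  m <- mass[cells]
  if (fraction >= 1) return(cells)
  target <- fraction * sum(m)
  ord <- order(m, decreasing = TRUE)
  got <- 0
  keep <- logical(length(cells))
  for (k in ord) {
    if (got + m[k] <= target + 1e-9 * target) {
      keep[k] <- TRUE
      got <- got + m[k]
    }
  }
  cells[keep]
}

#' Construct a synthetic dataset with a known outside-SCS fraction
#'
#' Ground-truth oracle for the SCS pipeline. Generates a baseline scenario,
#' builds the crop SCS at the given coverage and binning, then displaces the
#' future climate of a cell subset carrying fraction `f` of total crop
#' production far outside the baseline production cloud (precipitation at
#' the axis lower bound, biotemperature forced to zero, i.e. the frozen apex
#' of the chart); all other cells' future equals the baseline. The displaced
#' subset takes fraction `f` from the cells inside the SCS and fraction `f`
#' from those outside it, so the displaced mass is `f` of the total *and*
#' the outside-share statistic recovers `f` despite the 5% baseline filter
#' on its denominator.
#'
#' @param f requested displaced production fraction in \[0, 1\].
#' @param spec a [scenario_spec()]; its warming/multipliers are ignored
#'   (futures start from the baseline).
#' @param concentration production concentration (see
#'   [generate_production()]).
#' @param coverage,bins SCS parameters used to define the strata.
#' @return List: `spec`, `grid`, `baseline`, `futures` (per-GCM
#'   [monthly_climate()]), `production`, `resilience`, `countries`, `mask`
#'   (baseline crop SCS) and `truth` (class `ground_truth`: `requested`,
#'   `fraction` = displaced mass / total mass, `cells` displaced indices).
#' @export
make_known_outside_scenario <- function(f, spec = scenario_spec(),
                                        concentration = 4,
                                        coverage = 0.95, bins = c(60, 60)) {
  if (!is.finite(f) || f < 0 || f > 1) stop("f must lie in [0, 1]")
  clim <- generate_climate(spec)
  ind <- climate_indicators(clim$baseline)
  prod <- generate_production(spec$seed + 1L, ind,
                              concentration = concentration)
  resil <- generate_resilience(spec$seed + 2L, clim$grid)
  countries <- generate_countries(spec$seed + 3L, clim$grid)
  tri <- to_triangle(ind$P, ind$R)
  mask <- build_scs(tri, prod$crop, coverage = coverage, bins = bins,
                    sector = "crop")
  member <- scs_contains(mask, tri) & prod$crop > 0
  prod_cells <- which(prod$crop > 0)
  cells <- c(
    .select_mass_fraction(prod$crop, which(member), f),
    .select_mass_fraction(prod$crop, setdiff(prod_cells, which(member)), f))
  if (f >= 1) cells <- prod_cells
  futures <- lapply(seq_len(spec$n_gcm), function(g) {
    fut <- clim$baseline
    fut$period <- "2081-2100"; fut$scenario <- "displaced"
    fut$gcm <- sprintf("gcm%02d", g)
    if (length(cells)) {
      ncell <- spec$nlat * spec$nlon
      for (m in 1:12) {
        idx <- cells + (m - 1L) * ncell
        fut$prec[idx] <- HLZ_P_MIN / 12
        fut$tmin[idx] <- -5
        fut$tmax[idx] <- -1
      }
    }
    fut
  })
  names(futures) <- sprintf("gcm%02d", seq_len(spec$n_gcm))
  truth <- structure(list(
    requested = f,
    fraction = sum(prod$crop[cells]) / sum(prod$crop),
    cells = cells), class = "ground_truth")
  list(spec = spec, grid = clim$grid, baseline = clim$baseline,
       futures = futures, production = prod, resilience = resil,
       countries = countries, mask = mask, truth = truth)
}
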