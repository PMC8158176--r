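# Holdridge triangle geometry: log2 axes for annual precipitation P and the
# PET ratio R, Cartesian chart coordinates, the hexagon-centroid lattice of
# the 38 base life zones, and the 13-class aggregation.

# Axis bounds of the Holdridge chart. Both axes span 8 octaves
# (16000/62.5 = 32/0.125 = 2^8), which is why the normalized coordinates
# divide by the constant 8.
HLZ_P_MIN <- 62.5
HLZ_P_MAX <- 16000
HLZ_R_MIN <- 0.125
HLZ_R_MAX <- 32
HLZ_OCTAVES <- 8

# PET (mm/yr) per degree C of biotemperature (Holdridge's constant).
PET_PER_DEGREE <- 58.93

# (X, Y) distance between adjacent same-row hexagon centroids: one octave on
# each log2 axis in opposite directions at fixed biotemperature. Change
# magnitudes are expressed in units of this spacing.
HLZ_CENTROID_SPACING <- 0.125

#' Map precipitation and PET ratio to Holdridge-triangle coordinates
#'
#' Places a cell in the Holdridge chart. Axes are log2-scaled and normalized
#' to \[0, 1\] over their 8-octave spans (precipitation 62.5--16000 mm,
#' PET ratio 0.125--32):
#' `P' = (log2 P - log2 62.5) / 8`, `R' = (log2 R - log2 0.125) / 8`, then
#' `X = 0.5 * (1 + P' - R')`, `Y = 1 - P' - R'`. Values beyond the axis
#' bounds (including zero precipitation or a zero PET ratio, as in fully
#' frozen cells) are clamped to the bounds so that hyper-arid, hyper-humid
#' and polar cells stay classifiable; negative or non-finite inputs become
#' no-data. Lines of constant `Y` are lines of constant biotemperature.
#'
#' @param P annual precipitation, mm/yr (any shape; vector, matrix).
#' @param R PET ratio (dimensionless), same shape as `P`.
#' @return Object of class `triangle_points`: list of `Pp`, `Rp`, `X`, `Y`,
#'   each with the shape of the input.
#' @examples
#' to_triangle(1000, 2)  # center of the chart: X = 0.5, Y = 0
#' @export
to_triangle <- function(P, R) {
  if (!is.null(dim(P)) || !is.null(dim(R)))
    stopifnot(identical(dim(P), dim(R)))
  bad <- !is.finite(P) | !is.finite(R) | P < 0 | R < 0
  Pc <- pmin(pmax(P, HLZ_P_MIN), HLZ_P_MAX)
  Rc <- pmin(pmax(R, HLZ_R_MIN), HLZ_R_MAX)
  Pp <- (log2(Pc) - log2(HLZ_P_MIN)) / HLZ_OCTAVES
  Rp <- (log2(Rc) - log2(HLZ_R_MIN)) / HLZ_OCTAVES
  Pp[bad] <- NA_real_
  Rp[bad] <- NA_real_
  out <- list(Pp = Pp, Rp = Rp,
              X = 0.5 * (1 + Pp - Rp),
              Y = 1 - Pp - Rp)
  class(out) <- "triangle_points"
  out
}

#' @export
print.triangle_points <- function(x, ...) {
  n <- length(x$X)
  cat(sprintf("<triangle_points> %d points (%d no-data)\n",
              n, sum(!is.finite(x$X))))
  invisible(x)
}

# ---- base-zone lattice ------------------------------------------------------

# The 38 base zones sit on the half-integer log2 lattice: hexagon centroids at
# P' = (i + 0.5)/8, R' = (j + 0.5)/8 for i + j <= 7. Diagonal s = i + j indexes
# the biotemperature row (biotemperature doubles per step down the chart, with
# the critical lines 1.5/3/6/12/24 C falling exactly on half-octave levels).
# Rows s <= 2 merge into a single polar-desert zone; row s = 6 exists twice,
# split by the frost line into warm temperate (frost) and subtropical
# (frost free).

.hlz_row_names <- c("polar", "subpolar", "boreal", "cool temperate",
                    "warm temperate", "subtropical", "tropical")

# Humidity-province names per row, ordered from most arid (j = s) to most
# humid (j = 0).
.hlz_provinces <- list(
  subpolar = c("dry tundra", "moist tundra", "wet tundra", "rain tundra"),
  boreal = c("desert", "dry scrub", "moist forest", "wet forest",
             "rain forest"),
  `cool temperate` = c("desert", "desert scrub", "steppe", "moist forest",
                       "wet forest", "rain forest"),
  `warm temperate` = c("desert", "desert scrub", "thorn steppe", "dry forest",
                       "moist forest", "wet forest", "rain forest"),
  subtropical = c("desert", "desert scrub", "thorn woodland", "dry forest",
                  "moist forest", "wet forest", "rain forest"),
  tropical = c("desert", "desert scrub", "thorn woodland", "very dry forest",
               "dry forest", "moist forest", "wet forest", "rain forest")
)

#' Base Holdridge life zone table
#'
#' The 38 base life zones with their chart geometry: biotemperature row,
#' humidity province, frost regime (row 12--24 C splits into warm temperate
#' under frost and subtropical when frost free), hexagon-centroid coordinates
#' on the half-integer log2 lattice, and the aggregated class each zone maps
#' to. The six lattice cells above the 1.5 C line collapse into the single
#' polar desert zone, whose nominal centroid is the topmost cell.
#'
#' @return data.frame with one row per base zone: `base_id`, `base_name`,
#'   `row` (diagonal index), `p_idx`, `r_idx` (octave indices), `frost`
#'   (`"frost"`, `"frost_free"` or `NA`), `Pp`, `Rp`, `X`, `Y` (centroid),
#'   `agg_id`.
#' @export
hlz_zones <- function() {
  rows <- list()
  add <- function(base_id, name, s, i, j, frost, agg_id) {
    Pp <- (i + 0.5) / HLZ_OCTAVES
    Rp <- (j + 0.5) / HLZ_OCTAVES
    rows[[length(rows) + 1L]] <<- data.frame(
      base_id = base_id, base_name = name, row = s, p_idx = i, r_idx = j,
      frost = frost, Pp = Pp, Rp = Rp,
      X = 0.5 * (1 + Pp - Rp), Y = 1 - Pp - Rp,
      agg_id = agg_id, stringsAsFactors = FALSE)
  }
  # polar desert: single zone, nominal centroid at the apex cell (0, 0)
  add(1L, "polar desert", 0L, 0L, 0L, NA_character_, 1L)
  id <- 2L
  specs <- list(
    list(s = 3L, prefix = "subpolar",      frost = NA_character_),
    list(s = 4L, prefix = "boreal",        frost = NA_character_),
    list(s = 5L, prefix = "cool temperate", frost = NA_character_),
    list(s = 6L, prefix = "warm temperate", frost = "frost"),
    list(s = 6L, prefix = "subtropical",   frost = "frost_free"),
    list(s = 7L, prefix = "tropical",      frost = NA_character_)
  )
  agg <- hlz_aggregation_default()
  for (sp in specs) {
    prov <- .hlz_provinces[[sp$prefix]]
    s <- sp$s
    for (k in seq_along(prov)) {
      j <- s - (k - 1L)           # from most arid to most humid
      i <- s - j
      name <- paste(sp$prefix, prov[k])
      add(id, name, s, i, j, sp$frost, agg$agg_id[match(id, agg$base_id)])
      id <- id + 1L
    }
  }
  do.call(rbind, rows)
}

# Default 38 -> 13 aggregation (Leemans-style, with the two tropical dry-side
# forest classes merged into tropical dry forest).
hlz_aggregation_default <- function() {
  agg_of <- c(
    1L,                               # polar desert
    2L, 2L, 2L, 2L,                   # tundra
    3L, 3L, 4L, 4L, 4L,               # boreal desert / boreal forest
    5L, 5L, 6L, 7L, 7L, 7L,           # cool temperate
    5L, 5L, 6L, 7L, 7L, 7L, 7L,       # warm temperate
    8L, 8L, 9L, 9L, 10L, 10L, 10L,    # subtropical
    11L, 11L, 12L, 12L, 12L, 13L, 13L, 13L)  # tropical
  data.frame(base_id = seq_len(38L), agg_id = agg_of)
}

#' Aggregated life-zone legend (13 classes)
#'
#' @param aggregation optional custom aggregation table as returned by
#'   [hlz_aggregation()].
#' @return data.frame `agg_id`, `agg_name`, `color` (hex).
#' @export
hlz_legend <- function(aggregation = NULL) {
  legend <- data.frame(
    agg_id = 1:13,
    agg_name = c("polar desert", "tundra", "boreal desert", "boreal forest",
                 "temperate desert", "temperate steppe", "temperate forest",
                 "subtropical desert", "subtropical dry forest",
                 "subtropical moist forest", "tropical desert",
                 "tropical dry forest", "tropical moist forest"),
    color = c("#ffffff", "#c1d7e8", "#e8e4c9", "#2e6e4e",
              "#e0c27d", "#c9d96e", "#4f9153",
              "#e8a25e", "#b8c45a", "#6fae62",
              "#d96c2e", "#a8b83c", "#1e7a3c"),
    stringsAsFactors = FALSE)
  if (!is.null(aggregation)) {
    keep <- sort(unique(aggregation$agg_id))
    legend <- legend[legend$agg_id %in% keep, , drop = FALSE]
  }
  legend
}

#' Read or fetch the base-to-aggregated zone mapping
#'
#' The packaged default (installed as `extdata/hlz_aggregation.csv`) follows
#' the Leemans-style aggregation to 13 classes. Supply `path` to override
#' with an edited copy.
#'
#' @param path optional CSV with columns `base_id`, `agg_id`.
#' @return data.frame with `base_id`, `agg_id`.
#' @export
hlz_aggregation <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hlz_aggregation.csv", package = "climspace")
  if (!nzchar(path) || !file.exists(path))
    return(hlz_aggregation_default())
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("base_id", "agg_id") %in% names(tab)))
    stop("aggregation table needs columns base_id, agg_id")
  tab[, c("base_id", "agg_id")]
}

# Lattice used for nearest-centroid assignment: one row per hexagon cell
# (36 cells, i + j <= 7), with the base id under each frost regime. Ordered by
# ascending base id so that "first nearest" implements the lowest-id tie-break.
hlz_lattice <- function() {
  zones <- hlz_zones()
  cells <- expand.grid(i = 0:7, j = 0:7)
  cells <- cells[cells$i + cells$j <= 7L, ]
  cells$s <- cells$i + cells$j
  base_frost <- base_nofrost <- integer(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    s <- cells$s[k]
    if (s <= 2L) {
      base_frost[k] <- base_nofrost[k] <- 1L
    } else if (s == 6L) {
      wt <- zones[zones$row == 6L & zones$frost %in% "frost" &
                    zones$p_idx == cells$i[k], "base_id"]
      st <- zones[zones$row == 6L & zones$frost %in% "frost_free" &
                    zones$p_idx == cells$i[k], "base_id"]
      base_frost[k] <- wt
      base_nofrost[k] <- st
    } else {
      base_frost[k] <- base_nofrost[k] <-
        zones[zones$row == s & zones$p_idx == cells$i[k], "base_id"]
    }
  }
  Pp <- (cells$i + 0.5) / HLZ_OCTAVES
  Rp <- (cells$j + 0.5) / HLZ_OCTAVES
  out <- data.frame(i = cells$i, j = cells$j, s = cells$s, Pp = Pp, Rp = Rp,
                    X = 0.5 * (1 + Pp - Rp), Y = 1 - Pp - Rp,
                    base_frost = base_frost, base_nofrost = base_nofrost)
  out[order(out$base_frost, out$base_nofrost), ]
}

#' Classify triangle points into Holdridge life zones
#'
#' Assigns each point to the nearest hexagon centroid in `(X, Y)` (ties go to
#' the lowest zone id). For the 12--24 C biotemperature row the frost flag
#' resolves warm temperate (any frost month) versus subtropical (frost free);
#' base zones are then mapped through the aggregation table to the 13
#' aggregated classes.
#'
#' @param points a [to_triangle()] result (any shape).
#' @param frost_free logical, same shape: `TRUE` where all monthly minimum
#'   temperatures stay above 0 C.
#' @param level `"aggregated"` (default, ids 1--13) or `"base"` (ids 1--38).
#' @param aggregation optional custom mapping from [hlz_aggregation()].
#' @return Integer zone ids with the shape of the input; `NA` for no-data
#'   points. Attribute `legend` carries the id-to-name table in use.
#' @examples
#' pt <- to_triangle(1000, 2)
#' classify_zone(pt, frost_free = FALSE)
#' @export
classify_zone <- function(points, frost_free, level = c("aggregated", "base"),
                          aggregation = NULL) {
  level <- match.arg(level)
  lat <- hlz_lattice()
  X <- as.vector(points$X); Y <- as.vector(points$Y)
  ff <- as.vector(frost_free)
  if (length(ff) == 1L) ff <- rep(ff, length(X))
  stopifnot(length(ff) == length(X))
  ok <- is.finite(X) & is.finite(Y)
  base <- rep(NA_integer_, length(X))
  if (any(ok)) {
    d2 <- outer(X[ok], lat$X, "-")^2 + outer(Y[ok], lat$Y, "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    bf <- lat$base_frost[nearest]
    bn <- lat$base_nofrost[nearest]
    base[ok] <- ifelse(!is.na(ff[ok]) & ff[ok], bn, bf)
  }
  out <- if (level == "base") {
    attr(base, "legend") <- hlz_zones()[, c("base_id", "base_name")]
    base
  } else {
    agg <- if (is.null(aggregation)) hlz_aggregation_default() else aggregation
    ids <- agg$agg_id[match(base, agg$base_id)]
    attr(ids, "legend") <- hlz_legend(agg)
    ids
  }
  if (!is.null(dim(points$X))) {
    lg <- attr(out, "legend")
    dim(out) <- dim(points$X)
    attr(out, "legend") <- lg
  }
  out
}

#' Tabulate zone areas
#'
#' Sums cell areas per zone id, the bookkeeping behind statements such as the
#' boreal forest shrinking from 18.0 to 8.0 million km^2.
#'
#' @param zones integer zone-id matrix (from [classify_zone()]).
#' @param areas matching cell-area matrix (km^2, from [cell_areas()]).
#' @return data.frame `zone_id`, `zone_name` (when a legend is attached),
#'   `area_km2`, sorted by id. No-data cells are excluded.
#' @export
zone_areas <- function(zones, areas) {
  check_same_shape(zones, areas, what = "zone/area grids")
  ok <- !is.na(zones)
  tot <- tapply(areas[ok], zones[ok], sum)
  out <- data.frame(zone_id = as.integer(names(tot)),
                    area_km2 = as.numeric(tot))
  legend <- attr(zones, "legend")
  if (!is.null(legend)) {
    idcol <- intersect(c("agg_id", "base_id"), names(legend))[1]
    namecol <- intersect(c("agg_name", "base_name"), names(legend))[1]
    out$zone_name <- legend[[namecol]][match(out$zone_id, legend[[idcol]])]
    out <- out[, c("zone_id", "zone_name", "area_km2")]
  }
  out[order(out$zone_id), ]
}
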