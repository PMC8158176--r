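# Regular lat-lon grid handling. All gridded fields in the package are plain
# matrices [nlat x nlon], row 1 = northernmost row, column 1 = westernmost
# column; coordinates refer to cell centers.

EARTH_RADIUS_KM <- 6371.0088

#' Define a regular latitude-longitude grid
#'
#' Cell-center coordinates for a regular grid. Latitude runs north to south
#' (descending), longitude west to east over \[-180, 180\]; matrices indexed
#' `[lat, lon]`.
#'
#' @param nlat,nlon number of rows (latitude bands) and columns.
#' @param lat_max northern/southern extent in degrees; the grid spans
#'   `[-lat_max, lat_max]`.
#' @return An object of class `cs_grid`: list with `lat`, `lon` (cell-center
#'   coordinate vectors), `dlat`, `dlon` (cell sizes in degrees).
#' @examples
#' g <- cs_grid(18, 36)
#' length(g$lat)
#' @export
cs_grid <- function(nlat = 90L, nlon = 180L, lat_max = 85) {
  if (nlat < 2 || nlon < 2)
    stop("grid must have at least 2 rows and 2 columns (got ",
         nlat, " x ", nlon, ")")
  if (lat_max <= 0 || lat_max > 90)
    stop("lat_max must be in (0, 90]")
  dlat <- 2 * lat_max / nlat
  dlon <- 360 / nlon
  structure(list(
    lat  = lat_max - (seq_len(nlat) - 0.5) * dlat,
    lon  = -180 + (seq_len(nlon) - 0.5) * dlon,
    dlat = dlat,
    dlon = dlon
  ), class = "cs_grid")
}

#' @export
print.cs_grid <- function(x, ...) {
  cat(sprintf("<cs_grid> %d x %d cells, lat %.3f..%.3f, lon %.3f..%.3f\n",
              length(x$lat), length(x$lon),
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

#' Geodesic cell areas for a regular lat-lon grid
#'
#' Area of each grid cell in km^2 from the spherical-band formula
#' `A = R^2 * dlon * (sin(lat_n) - sin(lat_s))`, so area is proportional to
#' the cosine of latitude and symmetric about the equator. These areas are the
#' weights behind every "area-weighted" quantile in the risk classification.
#'
#' @param grid a [cs_grid()], or a numeric vector of cell-center latitudes
#'   (in which case `dlat` and `dlon` must be given).
#' @param dlat,dlon cell size in degrees, ignored when `grid` is a `cs_grid`.
#' @return Matrix `[nlat x nlon]` of areas (km^2); constant along rows.
#' @examples
#' a <- cell_areas(cs_grid(90, 180, lat_max = 90))
#' sum(a) / 5.1e8  # close to 1: full sphere
#' @export
cell_areas <- function(grid, dlat = NULL, dlon = NULL) {
  if (inherits(grid, "cs_grid")) {
    lat <- grid$lat; dlat <- grid$dlat; dlon <- grid$dlon
    nlon <- length(grid$lon)
  } else {
    lat <- as.numeric(grid)
    if (is.null(dlat) || is.null(dlon))
      stop("dlat and dlon are required when grid is a latitude vector")
    nlon <- round(360 / dlon)
  }
  if (any(abs(lat) > 90)) stop("latitudes outside [-90, 90]")
  north <- pmin(lat + dlat / 2, 90) * pi / 180
  south <- pmax(lat - dlat / 2, -90) * pi / 180
  band <- EARTH_RADIUS_KM^2 * (dlon * pi / 180) * (sin(north) - sin(south))
  matrix(band, nrow = length(lat), ncol = nlon)
}

# Two grids describe the same raster geometry (within floating tolerance).
same_grid <- function(a, b, tol = 1e-8) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    max(abs(a$lat - b$lat)) < tol && max(abs(a$lon - b$lon)) < tol
}

# Abort unless all supplied matrices share the reference grid shape.
check_same_shape <- function(ref, ..., what = "grids") {
  dims <- lapply(list(...), dim)
  for (d in dims)
    if (is.null(d) || !all(d == dim(ref)))
      stop("misaligned ", what, ": expected ", paste(dim(ref), collapse = " x "),
           ", got ", paste(d, collapse = " x "),
           "; inputs must share one grid (no silent resampling)")
  invisible(TRUE)
}

# Collapse an [nlat, nlon, 12] array to a [ncell x 12] matrix (month in cols).
month_matrix <- function(a) {
  stopifnot(length(dim(a)) == 3L, dim(a)[3] == 12L)
  dim(a) <- c(prod(dim(a)[1:2]), 12L)
  a
}
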