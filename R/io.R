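# Plain-text raster and table I/O. Single-band grids travel as ASCII grid
# (.asc) files -- the plain-text raster format with a 6-line header -- with a
# dx/dy header extension for non-square cells; monthly climate stacks travel
# as one .asc per variable-month plus a key-value manifest. Round-trips
# preserve values (exactly for integers, to 15 significant digits for
# floating grids), the no-data mask, and the grid coordinates.

#' Write a grid as a plain-text ASCII raster
#'
#' @param x numeric or integer matrix `[nlat x nlon]`, row 1 northernmost.
#' @param path output file (conventionally `.asc`).
#' @param grid the [cs_grid()] describing `x`.
#' @param nodata value standing in for `NA` in the file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, grid, nodata = -9999) {
  check_same_shape(matrix(0, length(grid$lat), length(grid$lon)), x,
                   what = "raster/grid")
  hdr <- c(
    sprintf("ncols %d", ncol(x)),
    sprintf("nrows %d", nrow(x)),
    sprintf("xllcorner %.10g", min(grid$lon) - grid$dlon / 2),
    sprintf("yllcorner %.10g", min(grid$lat) - grid$dlat / 2),
    if (isTRUE(all.equal(grid$dlat, grid$dlon)))
      sprintf("cellsize %.10g", grid$dlon)
    else c(sprintf("dx %.10g", grid$dlon), sprintf("dy %.10g", grid$dlat)),
    sprintf("NODATA_value %.10g", nodata))
  v <- x
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(v, digits = 15, trim = TRUE, scientific = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text ASCII raster
#'
#' @param path an `.asc` file written by [write_raster()] (or any
#'   ASCII-grid file with an `ncols/nrows/xllcorner/yllcorner/
#'   cellsize-or-dx-dy/NODATA_value` header).
#' @return List with `values` (matrix, `NA` where no-data), `grid`
#'   (a [cs_grid()]-compatible list) and `nodata`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path, n = 7L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && !is.na(suppressWarnings(as.numeric(parts[2]))) &&
        grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr)))
    stop("not an ASCII grid (missing header fields): ", path)
  dlon <- hdr$dx %||% hdr$cellsize
  dlat <- hdr$dy %||% hdr$cellsize
  if (is.null(dlon)) stop("no cellsize/dx/dy header in ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  v <- scan(path, skip = nhdr, quiet = TRUE)
  if (length(v) != nr * nc)
    stop("raster body size mismatch in ", path)
  m <- matrix(v, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid <- structure(list(
    lat = hdr$yllcorner + dlat * (nr - seq_len(nr) + 0.5),
    lon = hdr$xllcorner + dlon * (seq_len(nc) - 0.5),
    dlat = dlat, dlon = dlon), class = "cs_grid")
  list(values = m, grid = grid, nodata = hdr$nodata_value %||% NA)
}

#' Write / read a key-value manifest
#'
#' Flat `key = value` text files recording seeds and parameters alongside
#' generated rasters. Lines starting with `#` and `[section]` headers are
#' ignored on read.
#'
#' @param x named list of atomic values.
#' @param path file path.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: named list
#'   of character values (numbers not coerced).
#' @export
write_manifest <- function(x, path) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  writeLines(sprintf("%s = %s", names(x),
                     vapply(x, function(v) paste(format(v, digits = 15),
                                                 collapse = ","),
                            character(1))), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "[")]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- lapply(kv, function(p) paste(p[-1], collapse = "="))
  names(out) <- vapply(kv, `[[`, character(1), 1L)
  out
}

#' Write / read a monthly climate stack as per-month ASCII rasters
#'
#' Writes 36 `.asc` files (`prec_01.asc` ... `tmax_12.asc`) plus a
#' `manifest.txt` into `dir`.
#'
#' @param clim a [monthly_climate()].
#' @param dir target directory (created if needed).
#' @return `dir` invisibly / the reconstructed [monthly_climate()].
#' @export
write_monthly_climate <- function(clim, dir) {
  stopifnot(inherits(clim, "monthly_climate"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (var in c("prec", "tmin", "tmax"))
    for (m in 1:12)
      write_raster(clim[[var]][, , m],
                   file.path(dir, sprintf("%s_%02d.asc", var, m)), clim$grid)
  write_manifest(list(period = clim$period, scenario = clim$scenario,
                      gcm = clim$gcm), file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname write_monthly_climate
#' @export
read_monthly_climate <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.txt"))
  first <- read_raster(file.path(dir, "prec_01.asc"))
  grid <- first$grid
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  get <- function(var) {
    a <- array(NA_real_, c(nlat, nlon, 12))
    for (m in 1:12) {
      r <- read_raster(file.path(dir, sprintf("%s_%02d.asc", var, m)))
      if (!same_grid(r$grid, grid))
        stop("misaligned grid in ", sprintf("%s_%02d.asc", var, m),
             " (refusing to resample)")
      a[, , m] <- r$values
    }
    a
  }
  monthly_climate(get("prec"), get("tmin"), get("tmax"), grid,
                  period = man$period %||% "unknown",
                  scenario = man$scenario %||% "unknown",
                  gcm = man$gcm %||% "none")
}
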