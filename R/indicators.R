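# Holdridge input variables from monthly climate: annual precipitation,
# biotemperature (sub-zero months contribute zero; no upper cap), PET via the
# 58.93 mm/yr/C constant, the PET ratio, and the frost mask.

#' Monthly climate stack
#'
#' Container for a 12-month precipitation / minimum / maximum temperature
#' stack on a regular lat-lon grid, tagged with period, scenario and model
#' labels.
#'
#' @param prec,tmin,tmax arrays `[nlat, nlon, 12]`: precipitation (mm/month)
#'   and monthly minimum / maximum temperature (deg C).
#' @param grid the [cs_grid()] the fields live on.
#' @param period,scenario,gcm free-text labels.
#' @return Object of class `monthly_climate`.
#' @export
monthly_climate <- function(prec, tmin, tmax, grid,
                            period = "baseline", scenario = "historical",
                            gcm = "none") {
  for (a in list(prec, tmin, tmax))
    if (length(dim(a)) != 3L || dim(a)[3] != 12L)
      stop("monthly fields must be [nlat, nlon, 12] arrays")
  stopifnot(identical(dim(prec), dim(tmin)), identical(dim(prec), dim(tmax)))
  if (dim(prec)[1] != length(grid$lat) || dim(prec)[2] != length(grid$lon))
    stop("field dimensions do not match the grid")
  if (any(prec < 0, na.rm = TRUE)) stop("negative monthly precipitation")
  if (any(tmin > tmax, na.rm = TRUE)) stop("tmin exceeds tmax in some cells")
  structure(list(prec = prec, tmin = tmin, tmax = tmax, grid = grid,
                 period = period, scenario = scenario, gcm = gcm),
            class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  cat(sprintf("<monthly_climate> %d x %d x 12 [%s / %s / %s]\n",
              dim(x$prec)[1], dim(x$prec)[2], x$period, x$scenario, x$gcm))
  invisible(x)
}

#' Annual precipitation
#'
#' Sum of the 12 monthly totals, mm/yr. A missing month marks the cell
#' no-data.
#'
#' @param prec `[nlat, nlon, 12]` array or `[n x 12]` matrix of monthly
#'   precipitation (mm/month).
#' @return Matrix (or vector) of annual totals.
#' @export
annual_precipitation <- function(prec) {
  if (length(dim(prec)) == 3L) {
    d <- dim(prec)[1:2]
    out <- rowSums(month_matrix(prec))  # NA if any month NA
    matrix(out, d[1], d[2])
  } else {
    m <- as.matrix(prec)
    if (ncol(m) != 12L) stop("need 12 monthly values")
    rowSums(m)
  }
}

#' Monthly mean temperature from the min/max midpoint
#'
#' Estimates monthly mean temperature as `(tmin + tmax)/2 + delta`, where
#' `delta` is an optional per-cell per-month additive bias correction
#' (see [baseline_offset()]); zero when the midpoint is taken at face value.
#' Cells with `tmin > tmax` are flagged invalid (NA).
#'
#' @param tmin,tmax monthly minimum / maximum temperature, same shape.
#' @param delta additive correction: scalar or an array matching `tmin`.
#' @return Monthly mean temperatures, same shape as `tmin`.
#' @export
monthly_mean_temperature <- function(tmin, tmax, delta = 0) {
  stopifnot(identical(dim(tmin), dim(tmax)))
  out <- (tmin + tmax) / 2 + delta
  out[which(tmin > tmax)] <- NA_real_
  out
}

#' Additive bias correction from baseline temperatures
#'
#' The monthly min/max midpoint is a biased estimate of the monthly mean.
#' When the baseline period supplies all three (mean, min, max), the bias is
#' corrected additively: `delta_m = mean_m - (min_m + max_m)/2`, computed per
#' cell and month from the baseline and then applied to every future
#' midpoint of the same cell and month.
#'
#' @param tmean,tmin,tmax baseline monthly fields, same shape.
#' @return The per-cell per-month offset array `delta`.
#' @export
baseline_offset <- function(tmean, tmin, tmax) {
  stopifnot(identical(dim(tmean), dim(tmin)), identical(dim(tmean), dim(tmax)))
  tmean - (tmin + tmax) / 2
}

#' Biotemperature
#'
#' Annual biotemperature: monthly means below 0 C contribute zero and the
#' divisor stays 12 (the original zero-substitution convention), so polar
#' cells tend to 0 rather than being dropped. No upper cap is applied --
#' months above 30 C enter at face value.
#'
#' @param tmean `[nlat, nlon, 12]` array or `[n x 12]` matrix of monthly mean
#'   temperature (deg C).
#' @return Matrix (or vector) of biotemperature, deg C, `>= 0`.
#' @export
biotemperature <- function(tmean) {
  if (length(dim(tmean)) == 3L) {
    d <- dim(tmean)[1:2]
    out <- rowSums(pmax(month_matrix(tmean), 0)) / 12
    matrix(out, d[1], d[2])
  } else {
    m <- as.matrix(tmean)
    if (ncol(m) != 12L) stop("need 12 monthly values")
    rowSums(pmax(m, 0)) / 12
  }
}

#' Annual potential evapotranspiration from biotemperature
#'
#' `PET = 58.93 * Tbio` (mm/yr), Holdridge's linear rule.
#'
#' @param tbio biotemperature, deg C (any shape).
#' @return PET, mm/yr, same shape.
#' @examples
#' pet(1)   # 58.93
#' @export
pet <- function(tbio) {
  if (any(tbio < 0, na.rm = TRUE)) stop("biotemperature must be >= 0")
  PET_PER_DEGREE * tbio
}

#' PET ratio (aridity)
#'
#' `R = PET / P`; values above 1 mean climatic water demand exceeds supply.
#' Cells with zero annual precipitation are assigned the aridity-axis upper
#' bound (32) so hyper-arid cells stay classifiable as desert.
#'
#' @param PET annual potential evapotranspiration, mm/yr.
#' @param P annual precipitation, mm/yr.
#' @return PET ratio, dimensionless, same shape.
#' @export
pet_ratio <- function(PET, P) {
  if (any(PET < 0, na.rm = TRUE) || any(P < 0, na.rm = TRUE))
    stop("PET and P must be nonnegative")
  out <- PET / P
  out[which(P == 0)] <- HLZ_R_MAX
  out
}

#' Frost-free mask
#'
#' `TRUE` where every monthly minimum temperature is strictly above 0 C
#' (no frost in any month); a month at exactly 0 C counts as frost. Resolves
#' the warm-temperate / subtropical split of the Holdridge chart.
#'
#' @param tmin `[nlat, nlon, 12]` array or `[n x 12]` matrix of monthly
#'   minimum temperature.
#' @return Logical matrix (or vector).
#' @export
frost_free <- function(tmin) {
  if (length(dim(tmin)) == 3L) {
    d <- dim(tmin)[1:2]
    m <- month_matrix(tmin)
    matrix(do.call(pmin, as.data.frame(m)) > 0, d[1], d[2])
  } else {
    m <- as.matrix(tmin)
    if (ncol(m) != 12L) stop("need 12 monthly values")
    do.call(pmin, as.data.frame(m)) > 0
  }
}

#' Derive all Holdridge input indicators from a monthly climate stack
#'
#' Computes annual precipitation `P`, biotemperature `Tbio`, `PET`, the PET
#' ratio `R` and the frost-free mask in one pass. Any missing monthly input
#' marks every indicator no-data for that cell.
#'
#' @param clim a [monthly_climate()].
#' @param delta optional per-cell per-month additive bias correction for the
#'   min/max midpoint (see [baseline_offset()]); typically computed from
#'   baseline data and reused for futures.
#' @return Object of class `climate_indicators`: matrices `P`, `Tbio`, `PET`,
#'   `R`, `frost_free`, plus the `grid` and the source labels.
#' @export
climate_indicators <- function(clim, delta = 0) {
  stopifnot(inherits(clim, "monthly_climate"))
  tmean <- monthly_mean_temperature(clim$tmin, clim$tmax, delta)
  P <- annual_precipitation(clim$prec)
  Tbio <- biotemperature(tmean)
  PET <- pet(Tbio)
  R <- pet_ratio(PET, P)
  ff <- frost_free(clim$tmin)
  nodata <- is.na(P) | is.na(Tbio)
  P[nodata] <- Tbio[nodata] <- PET[nodata] <- R[nodata] <- NA_real_
  ff[nodata] <- NA
  structure(list(P = P, Tbio = Tbio, PET = PET, R = R, frost_free = ff,
                 grid = clim$grid, period = clim$period,
                 scenario = clim$scenario, gcm = clim$gcm),
            class = "climate_indicators")
}

#' @export
print.climate_indicators <- function(x, ...) {
  cat(sprintf(
    "<climate_indicators> %d x %d [%s / %s / %s]; Tbio %.1f..%.1f C, P %.0f..%.0f mm\n",
    nrow(x$P), ncol(x$P), x$period, x$scenario, x$gcm,
    min(x$Tbio, na.rm = TRUE), max(x$Tbio, na.rm = TRUE),
    min(x$P, na.rm = TRUE), max(x$P, na.rm = TRUE)))
  invisible(x)
}
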