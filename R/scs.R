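# Safe climatic space (SCS): the region of the Holdridge triangle holding a
# target share (default 95%) of current production mass, built by binning
# production over chart coordinates and discarding the smallest-mass bins;
# membership tests for future conditions, per-GCM outside shares, GCM
# agreement (likelihood) classes, and country aggregation.

#' Build the production-weighted safe climatic space
#'
#' Sums production mass into a regular `(X, Y)` bin grid over the triangle's
#' bounding box, then removes the smallest-mass bins until just under
#' `1 - coverage` of the total mass has been excluded. The retained bins hold
#' at least `coverage` of the mass, and removing the smallest retained bin
#' would drop below it (minimality).
#'
#' @param points [to_triangle()] positions of the baseline climate.
#' @param production matching production-mass matrix (kcal or AU); cells with
#'   zero or no-data production carry no mass.
#' @param coverage target mass share inside the SCS, in (0, 1); default 0.95.
#' @param bins bin counts `c(nx, ny)` over X in \[0, 1\] and Y in \[-1, 1\].
#' @param sector free-text label (`"crop"` or `"livestock"`).
#' @return Object of class `scs_mask`: logical `member` matrix `[nx x ny]`,
#'   `xedges`, `yedges`, `coverage`, `sector`, `inside_share` (achieved mass
#'   share), and the binned `mass` matrix.
#' @export
build_scs <- function(points, production, coverage = 0.95, bins = c(60, 60),
                      sector = "crop") {
  if (!(coverage > 0 && coverage < 1)) stop("coverage must be in (0, 1)")
  stopifnot(length(points$X) == length(production))
  xedges <- seq(0, 1, length.out = bins[1] + 1L)
  yedges <- seq(-1, 1, length.out = bins[2] + 1L)
  p <- as.vector(production)
  p[is.na(p)] <- 0
  ok <- is.finite(as.vector(points$X)) & p > 0
  if (sum(p[ok]) <= 0) stop("zero total production mass")
  ix <- bin_index(points$X[ok], xedges)
  iy <- bin_index(points$Y[ok], yedges)
  mass <- matrix(0, bins[1], bins[2])
  key <- (iy - 1L) * bins[1] + ix
  acc <- tapply(p[ok], key, sum)
  mass[as.integer(names(acc))] <- acc
  total <- sum(mass)
  ord <- order(mass)                      # ascending; empty bins first
  cum <- cumsum(mass[ord])
  drop <- cum <= (1 - coverage) * total + 1e-9 * total
  member <- matrix(TRUE, bins[1], bins[2])
  member[ord[drop]] <- FALSE
  member[mass == 0] <- FALSE
  structure(list(member = member, mass = mass, xedges = xedges,
                 yedges = yedges, coverage = coverage, sector = sector,
                 inside_share = sum(mass[member]) / total),
            class = "scs_mask")
}

# Bin index with the rightmost edge closed; positions outside the edges get 0.
bin_index <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  i[v < edges[1] | v > edges[length(edges)]] <- 0L
  i
}

#' @export
print.scs_mask <- function(x, ...) {
  cat(sprintf(
    "<scs_mask> %s: %d member bins (%d x %d), coverage target %.2f, inside %.4f\n",
    x$sector, sum(x$member), nrow(x$member), ncol(x$member),
    x$coverage, x$inside_share))
  invisible(x)
}

#' Test triangle positions for SCS membership
#'
#' @param mask an [build_scs()] mask.
#' @param points [to_triangle()] positions.
#' @return Logical, shape of the input: `TRUE` where the position falls in a
#'   member bin. Positions outside the bin grid (or no-data) are `FALSE`.
#' @export
scs_contains <- function(mask, points) {
  X <- as.vector(points$X); Y <- as.vector(points$Y)
  ix <- bin_index(X, mask$xedges)
  iy <- bin_index(Y, mask$yedges)
  inside <- ix > 0L & iy > 0L & !is.na(ix) & !is.na(iy)
  out <- logical(length(X))
  out[inside] <- mask$member[cbind(ix[inside], iy[inside])]
  out[!is.finite(X) | !is.finite(Y)] <- FALSE
  if (!is.null(dim(points$X))) dim(out) <- dim(points$X)
  out
}

#' Share of production falling outside the SCS under future conditions
#'
#' For each GCM, the production mass of cells whose future triangle position
#' leaves the SCS, as a share of the mass of the "major production areas" --
#' cells whose baseline position lies inside the mask (cells excluded by the
#' baseline 5% filter are excluded from the denominator). Summarized across
#' GCMs by the median and the 5th--95th percentile range.
#'
#' @param future_points list of [to_triangle()] results, one per GCM (a bare
#'   `triangle_points` object is treated as a single-member ensemble).
#' @param baseline_points [to_triangle()] result for the baseline.
#' @param production production-mass matrix aligned with the points.
#' @param mask [build_scs()] mask built from the same sector's baseline.
#' @param denominator `"inside_baseline"` (default): restrict to the major
#'   production areas, i.e. cells whose baseline position lies inside the
#'   mask, excluding the mass dropped by the baseline 5% filter;
#'   `"all_production"`: every production cell counts, which makes the share
#'   provably nonincreasing in the coverage target.
#' @return Object of class `scs_share`: `per_gcm` (named vector of shares in
#'   \[0, 1\]), `median`, `q05`, `q95`, `outside` (list of logical outside
#'   indicators per GCM over denominator cells), `denominator` (logical
#'   matrix of denominator cells).
#' @export
outside_scs_share <- function(future_points, baseline_points, production,
                              mask,
                              denominator = c("inside_baseline",
                                              "all_production")) {
  denominator <- match.arg(denominator)
  if (inherits(future_points, "triangle_points"))
    future_points <- list(future_points)
  p <- production
  p[is.na(p)] <- 0
  stopifnot(length(baseline_points$X) == length(p))
  denom <- if (denominator == "inside_baseline")
    scs_contains(mask, baseline_points) & p > 0
  else
    !is.na(p) & p > 0
  denom_mass <- sum(p[denom])
  if (denom_mass <= 0) stop("no production mass inside the baseline SCS")
  outside <- vector("list", length(future_points))
  shares <- numeric(length(future_points))
  for (g in seq_along(future_points)) {
    fp <- future_points[[g]]
    if (length(fp$X) != length(p))
      stop("future grid misaligned with production for GCM ", g)
    out_g <- denom & !scs_contains(mask, fp)
    outside[[g]] <- out_g
    shares[g] <- sum(p[out_g]) / denom_mass
  }
  names(shares) <- names(future_points) %||% paste0("gcm", seq_along(shares))
  structure(list(per_gcm = shares,
                 median = stats::median(shares),
                 q05 = unname(stats::quantile(shares, 0.05)),
                 q95 = unname(stats::quantile(shares, 0.95)),
                 outside = outside, denominator = denom),
            class = "scs_share")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scs_share <- function(x, ...) {
  cat(sprintf(
    "<scs_share> median %.1f%% outside SCS (5th-95th pct across %d GCMs: %.1f-%.1f%%)\n",
    100 * x$median, length(x$per_gcm), 100 * x$q05, 100 * x$q95))
  invisible(x)
}

SCS_LIKELIHOOD_LABELS <- c("very likely inside", "likely inside",
                           "potentially outside", "likely outside")

#' GCM-agreement likelihood of leaving the SCS
#'
#' Counts, per cell, how many GCMs place the cell's future conditions outside
#' the SCS and bins the count into the agreement categories used for an
#' 8-member ensemble: 0 (very likely inside), 1--3 (likely inside), 4--6
#' (potentially outside), 7--8 (likely outside).
#'
#' @param outside_list list of aligned logical matrices, one per GCM, `TRUE`
#'   where that GCM puts the cell outside the SCS.
#' @param n_gcm expected ensemble size; defaults to `length(outside_list)`
#'   and is checked against it.
#' @return List with `count` (integer matrix) and `category` (integer matrix
#'   1--4 with a `labels` attribute).
#' @export
likelihood_map <- function(outside_list, n_gcm = length(outside_list)) {
  if (length(outside_list) != n_gcm)
    stop("got ", length(outside_list), " GCM fields, expected ", n_gcm)
  d <- dim(outside_list[[1]])
  for (f in outside_list)
    if (!identical(dim(f), d)) stop("misaligned GCM outside fields")
  count <- Reduce(`+`, lapply(outside_list, function(m) m + 0L))
  # agreement bins for an 8-member ensemble: 0 / 1-3 / 4-6 / 7-8
  category <- 1L + (count >= 1) + (count >= 4) + (count >= 7)
  attr(category, "labels") <- SCS_LIKELIHOOD_LABELS
  list(count = count, category = category)
}

#' Aggregate SCS results to the national level
#'
#' Per-country production shares across the likelihood categories, the share
#' excluded by the baseline 5% filter ("no or minor production"), and the
#' country's median outside-SCS share across GCMs.
#'
#' @param share an [outside_scs_share()] result.
#' @param production production-mass matrix.
#' @param countries integer country-id matrix aligned with `production`; `NA`
#'   cells are skipped. When `NULL` a single global row is returned.
#' @param sector label copied to the output.
#' @return data.frame, one row per country: production totals, percentage of
#'   sector production per likelihood category, `no_or_minor` share, and
#'   `outside_share` (median across GCMs, % of the country's major
#'   production).
#' @export
country_aggregate <- function(share, production, countries = NULL,
                              sector = "crop") {
  p <- production
  p[is.na(p)] <- 0
  if (is.null(countries)) countries <- matrix(1L, nrow(p), ncol(p))
  check_same_shape(p, countries, what = "production/country grids")
  lk <- likelihood_map(share$outside)
  denom <- share$denominator
  ids <- sort(unique(countries[!is.na(countries)]))
  rows <- lapply(ids, function(cid) {
    in_c <- !is.na(countries) & countries == cid
    tot <- sum(p[in_c])
    if (tot <= 0) {
      cat_share <- rep(0, 4); minor <- 0; med_out <- NA_real_
    } else {
      cat_share <- vapply(1:4, function(k)
        100 * sum(p[in_c & denom & lk$category == k]) / tot, numeric(1))
      minor <- 100 * sum(p[in_c & !denom]) / tot
      cmass <- sum(p[in_c & denom])
      med_out <- if (cmass > 0)
        stats::median(vapply(share$outside, function(o)
          100 * sum(p[in_c & o]) / cmass, numeric(1)))
      else NA_real_
    }
    df <- data.frame(country = cid, sector = sector, production = tot,
                     t(cat_share), no_or_minor = minor,
                     outside_share = med_out)
    names(df)[4:7] <- gsub(" ", "_", SCS_LIKELIHOOD_LABELS)
    df
  })
  do.call(rbind, rows)
}
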