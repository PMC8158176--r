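# Production-weighted risk layer: animal units, area-weighted quantile
# classes, the 4 x 4 change-by-resilience production crosstab, and the
# high/critical risk zone labelling.

RISK_CLASS_LABELS <- c("low", "moderate", "high", "very high")

#' Animal-unit coefficients
#'
#' Head-to-animal-unit conversion factors for the seven major livestock
#' types (1 AU is roughly one cow): cattle 1.0, sheep 0.15, goats 0.10,
#' horses 1.8, buffalo 0.7, chickens 0.01, pigs 0.2.
#'
#' @return Named numeric vector, AU per head.
#' @export
animal_unit_coefficients <- function() {
  c(cattle = 1.0, sheep = 0.15, goats = 0.10, horses = 1.8,
    buffalo = 0.7, chickens = 0.01, pigs = 0.2)
}

#' Convert livestock headcounts to animal units
#'
#' `AU = sum over species of headcount x coefficient`, per cell.
#'
#' @param headcounts named list of nonnegative headcount matrices (or
#'   scalars); names must be a subset of the seven species in
#'   [animal_unit_coefficients()].
#' @return Matrix (or scalar) of animal units.
#' @examples
#' to_animal_units(list(buffalo = 1))       # 0.7
#' to_animal_units(list(chickens = 100))    # 1
#' @export
to_animal_units <- function(headcounts) {
  coefs <- animal_unit_coefficients()
  unknown <- setdiff(names(headcounts), names(coefs))
  if (length(unknown) || is.null(names(headcounts)))
    stop("unknown livestock species: ",
         paste(if (length(unknown)) unknown else "<unnamed>", collapse = ", "),
         " (expected ", paste(names(coefs), collapse = ", "), ")")
  au <- 0
  for (sp in names(headcounts)) {
    h <- headcounts[[sp]]
    if (any(h < 0, na.rm = TRUE)) stop("negative headcount for ", sp)
    au <- au + coefs[[sp]] * h
  }
  au
}

#' Area-weighted quantile
#'
#' Quantile of a field where each value's weight is its cell area: the
#' threshold is the smallest field value at which the weighted cumulative
#' distribution reaches the target probability.
#'
#' @param x numeric values.
#' @param w nonnegative weights, same length.
#' @param probs probabilities in (0, 1).
#' @return Numeric thresholds, one per probability.
#' @export
weighted_quantile <- function(x, w, probs) {
  ok <- is.finite(x) & is.finite(w) & w >= 0
  x <- x[ok]; w <- w[ok]
  if (!length(x) || sum(w) <= 0) stop("no usable values for weighted quantile")
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Classify a field into area-weighted quantile classes
#'
#' Divides a continuous field into low / moderate / high / very high classes
#' at the area-weighted 25/50/75th percentiles. When a previously derived
#' scheme is supplied its thresholds are reused without re-derivation -- the
#' rule that makes scenarios comparable (thresholds derived once from the
#' low-emissions reference and applied to the high-emissions field as well).
#' Class intervals are closed on the right at each threshold (a value equal
#' to the 25th-percentile threshold is "low"; a constant field is therefore
#' entirely "low").
#'
#' @param field numeric matrix.
#' @param areas matching cell-area matrix (weights).
#' @param scheme optional `quantile_scheme` whose thresholds are reused.
#' @param probs threshold probabilities when deriving a new scheme.
#' @param reference label recorded in a newly derived scheme.
#' @return List with `classes` (integer matrix, 1--4, labels attribute) and
#'   `scheme` (class `quantile_scheme`: `probs`, `thresholds`, `reference`).
#' @export
quantile_classes <- function(field, areas, scheme = NULL,
                             probs = c(0.25, 0.50, 0.75),
                             reference = "self") {
  check_same_shape(field, areas, what = "field/area grids")
  if (all(is.na(field))) stop("field is entirely no-data")
  if (is.null(scheme)) {
    thr <- weighted_quantile(as.vector(field), as.vector(areas), probs)
    scheme <- structure(list(probs = probs, thresholds = thr,
                             reference = reference),
                        class = "quantile_scheme")
  } else {
    stopifnot(inherits(scheme, "quantile_scheme"))
    thr <- scheme$thresholds
  }
  cl <- matrix(1L, nrow(field), ncol(field))
  for (t in thr) cl <- cl + (field > t)
  cl[is.na(field)] <- NA_integer_
  attr(cl, "labels") <- RISK_CLASS_LABELS
  list(classes = cl, scheme = scheme)
}

#' @export
print.quantile_scheme <- function(x, ...) {
  cat(sprintf("<quantile_scheme> ref '%s': %s\n", x$reference,
              paste(sprintf("p%02.0f=%.4g", 100 * x$probs, x$thresholds),
                    collapse = ", ")))
  invisible(x)
}

#' Risk-zone label for a change x resilience class combination
#'
#' Critical risk: resilience in its lowest quartile and Holdridge change in
#' its top quartile. High risk: resilience moderate with very high change, or
#' resilience low with high change (very high change with low resilience is
#' already critical; the two zones are mutually exclusive, critical taking
#' precedence). Everything else is "other".
#'
#' @param change_class,resilience_class integer class codes 1--4 or labels
#'   from `low/moderate/high/very high` (any shape).
#' @return Character `"critical"` / `"high"` / `"other"`, same shape.
#' @export
risk_zone_labels <- function(change_class, resilience_class) {
  as_code <- function(x) {
    if (is.character(x)) {
      m <- match(x, RISK_CLASS_LABELS)
      if (anyNA(m[!is.na(x)])) stop("unknown class label")
      m
    } else {
      if (any(!x %in% c(NA, 1:4))) stop("class codes must be 1..4")
      x
    }
  }
  ch <- as_code(change_class); re <- as_code(resilience_class)
  out <- rep(NA_character_, length(ch))
  ok <- !is.na(ch) & !is.na(re)
  crit <- ok & re == 1L & ch == 4L
  high <- ok & !crit & ((re == 2L & ch == 4L) | (re == 1L & ch >= 3L))
  out[ok] <- "other"
  out[high] <- "high"
  out[crit] <- "critical"
  if (!is.null(dim(change_class))) dim(out) <- dim(change_class)
  out
}

#' The full 4 x 4 risk-zone mapping table
#'
#' @return data.frame of every change x resilience class combination with its
#'   risk-zone label.
#' @export
risk_zone_matrix <- function() {
  g <- expand.grid(change_class = 1:4, resilience_class = 1:4)
  g$change_label <- RISK_CLASS_LABELS[g$change_class]
  g$resilience_label <- RISK_CLASS_LABELS[g$resilience_class]
  g$risk_zone <- risk_zone_labels(g$change_class, g$resilience_class)
  g
}

#' Cross-tabulate production over change and resilience classes
#'
#' Sums crop (kcal) and livestock (AU) production into the 16 combinations of
#' the four change classes and four resilience classes, normalized to
#' percentage shares of the classified global total per sector. Cells with
#' no-data in either classifier are excluded.
#'
#' @param change_classes,resilience_classes integer class matrices (1--4).
#' @param crop crop production matrix (kcal).
#' @param livestock livestock production matrix (AU).
#' @return Object of class `risk_table`: `crop` and `livestock` 4 x 4 share
#'   matrices (rows = change class, columns = resilience class, summing to
#'   100 over classified cells), plus `zones` (4 x 4 risk-zone labels) and
#'   per-sector `critical_share` / `high_share` /
#'   `high_or_critical_share` scalars.
#' @export
risk_crosstab <- function(change_classes, resilience_classes, crop, livestock) {
  check_same_shape(change_classes, resilience_classes, crop, livestock,
                   what = "classification/production grids")
  ok <- !is.na(change_classes) & !is.na(resilience_classes)
  tab_of <- function(prod) {
    p <- prod
    p[is.na(p)] <- 0
    tot <- sum(p[ok])
    if (tot <= 0) stop("no production mass on classified cells")
    m <- matrix(0, 4, 4,
                dimnames = list(change = RISK_CLASS_LABELS,
                                resilience = RISK_CLASS_LABELS))
    s <- tapply(p[ok], list(change_classes[ok], resilience_classes[ok]), sum)
    rr <- as.integer(rownames(s)); cc <- as.integer(colnames(s))
    for (a in seq_along(rr)) for (b in seq_along(cc))
      if (!is.na(s[a, b])) m[rr[a], cc[b]] <- s[a, b]
    100 * m / tot
  }
  crop_tab <- tab_of(crop)
  ls_tab <- tab_of(livestock)
  zones <- matrix(risk_zone_labels(rep(1:4, 4), rep(1:4, each = 4)), 4, 4,
                  dimnames = dimnames(crop_tab))
  shares <- function(tab) c(
    critical = sum(tab[zones == "critical"]),
    high = sum(tab[zones == "high"]),
    high_or_critical = sum(tab[zones %in% c("high", "critical")]))
  structure(list(crop = crop_tab, livestock = ls_tab, zones = zones,
                 crop_risk = shares(crop_tab), livestock_risk = shares(ls_tab)),
            class = "risk_table")
}

#' @export
print.risk_table <- function(x, digits = 1, ...) {
  cat("<risk_table> production shares (%), rows = change, cols = resilience\n")
  cat("crop:\n"); print(round(x$crop, digits))
  cat("livestock:\n"); print(round(x$livestock, digits))
  cat(sprintf("critical risk: crop %.1f%%, livestock %.1f%%\n",
              x$crop_risk["critical"], x$livestock_risk["critical"]))
  invisible(x)
}

#' Sensitivity of the critical-risk share to the resilience percentile
#'
#' Re-runs the critical-zone tabulation with the low-resilience threshold set
#' at each requested area-weighted percentile (the reported analysis varies
#' it from the 20th to the 30th), keeping the change classes fixed.
#'
#' @param change_classes integer change-class matrix (1--4).
#' @param resilience resilience field (continuous, -1..1).
#' @param areas cell-area matrix.
#' @param crop,livestock production matrices.
#' @param percentiles percentiles (in percent, within (0, 50)) at which the
#'   low-resilience threshold is drawn.
#' @return data.frame: `percentile`, `crop_share`, `livestock_share`
#'   (percent of sector production in the critical zone).
#' @export
resilience_sensitivity <- function(change_classes, resilience, areas,
                                   crop, livestock, percentiles = 20:30) {
  if (!length(percentiles)) stop("empty percentile list")
  if (any(percentiles <= 0 | percentiles >= 50))
    stop("percentiles must lie in (0, 50)")
  check_same_shape(change_classes, resilience, areas, crop, livestock)
  ok <- !is.na(change_classes) & !is.na(resilience)
  out <- lapply(percentiles, function(p) {
    thr <- weighted_quantile(resilience[ok], areas[ok], p / 100)
    crit <- ok & resilience <= thr & change_classes == 4L
    share <- function(prod) {
      prod[is.na(prod)] <- 0
      100 * sum(prod[crit]) / sum(prod[ok])
    }
    data.frame(percentile = p, crop_share = share(crop),
               livestock_share = share(livestock))
  })
  do.call(rbind, out)
}
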