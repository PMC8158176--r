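# Climatic change between baseline and future positions in the Holdridge
# triangle: centroid-normalized magnitude, dominant-driver direction, and
# GCM ensemble medians.

#' Magnitude of climatic change in centroid units
#'
#' Euclidean distance between the baseline and future chart positions in
#' `(X, Y)`, divided by the spacing between two adjacent same-row zone
#' centroids (0.125), so a value of 1 is the displacement needed to move from
#' the center of one zone to the next.
#'
#' @param base,future [to_triangle()] results on the same grid.
#' @return Numeric magnitudes (>= 0), shape of the input; NA where either
#'   point is no-data.
#' @export
change_magnitude <- function(base, future) {
  stopifnot(length(base$X) == length(future$X))
  sqrt((future$X - base$X)^2 + (future$Y - base$Y)^2) / HLZ_CENTROID_SPACING
}

#' Dominant driver and direction of climatic change
#'
#' Decomposes the displacement into normalized-axis components
#' `cP = dP'` (precipitation), `cR = dR'` (aridity) and
#' `cT = dP' + dR'` (biotemperature: along the chart geometry,
#' `log2 Tbio = log2 P + log2 R - log2 58.93`, so the biotemperature
#' component is the sum of the other two). The dominant driver is the
#' largest in absolute value (ties broken in the order T, R, P), signed to
#' one of six categories; zero displacement gives `"none"`.
#'
#' @param base,future [to_triangle()] results on the same grid.
#' @return Character categories (`"warmer"`, `"cooler"`, `"wetter"`,
#'   `"drier"`, `"more arid"`, `"less arid"`, `"none"`), shape of the input.
#' @export
change_direction <- function(base, future) {
  stopifnot(length(base$Pp) == length(future$Pp))
  cP <- as.vector(future$Pp - base$Pp)
  cR <- as.vector(future$Rp - base$Rp)
  cT <- cP + cR
  out <- rep(NA_character_, length(cP))
  ok <- is.finite(cP) & is.finite(cR)
  # tie-break order T, R, P: pick the first maximum
  comp <- cbind(T = abs(cT), R = abs(cR), P = abs(cP))
  comp[!ok, ] <- 0
  pick <- max.col(comp, ties.method = "first")
  lab <- character(length(cP))
  i1 <- which(pick == 1); i2 <- which(pick == 2); i3 <- which(pick == 3)
  lab[i1] <- ifelse(cT[i1] > 0, "warmer", "cooler")
  lab[i2] <- ifelse(cR[i2] > 0, "more arid", "less arid")
  lab[i3] <- ifelse(cP[i3] > 0, "wetter", "drier")
  lab[which(cP == 0 & cR == 0)] <- "none"
  out[ok] <- lab[ok]
  if (!is.null(dim(base$X))) dim(out) <- dim(base$X)
  out
}

#' Raw displacement vector between triangle positions
#'
#' The unreduced counterpart of [change_direction()]: chart-space
#' displacement and its angle, plus the three driver components.
#'
#' @inheritParams change_direction
#' @return List of `dX`, `dY`, `angle` (radians, atan2 convention), `cP`,
#'   `cR`, `cT`.
#' @export
change_vector <- function(base, future) {
  list(dX = future$X - base$X, dY = future$Y - base$Y,
       angle = atan2(future$Y - base$Y, future$X - base$X),
       cP = future$Pp - base$Pp, cR = future$Rp - base$Rp,
       cT = (future$Pp - base$Pp) + (future$Rp - base$Rp))
}

#' Per-cell median across a GCM ensemble
#'
#' Cell-wise median over aligned fields, with the usual even-count convention
#' (mean of the two middle order statistics). For the change map the median
#' is taken over each derived climate variable (P, Tbio, R) across GCMs
#' before triangle placement; per-GCM placement is kept for the SCS
#' likelihood analysis.
#'
#' @param fields list of aligned numeric matrices (one per GCM).
#' @return Matrix of per-cell medians.
#' @export
ensemble_median <- function(fields) {
  stopifnot(is.list(fields), length(fields) >= 1L)
  d <- dim(fields[[1]])
  for (f in fields)
    if (!identical(dim(f), d))
      stop("ensemble fields are misaligned")
  stack <- matrix(unlist(fields, use.names = FALSE), ncol = length(fields))
  out <- apply(stack, 1L, stats::median)
  matrix(out, d[1], d[2])
}

#' Ensemble-median climate indicators
#'
#' Medians of P, Tbio (PET and R re-derived from them), and a majority vote
#' for the frost-free mask, across a list of per-GCM [climate_indicators()].
#'
#' @param ind_list list of `climate_indicators` on one grid.
#' @return A `climate_indicators` object labelled `gcm = "ensemble-median"`.
#' @export
ensemble_median_indicators <- function(ind_list) {
  stopifnot(length(ind_list) >= 1L)
  P <- ensemble_median(lapply(ind_list, `[[`, "P"))
  Tbio <- ensemble_median(lapply(ind_list, `[[`, "Tbio"))
  PET <- pet(Tbio)
  R <- pet_ratio(PET, P)
  votes <- Reduce(`+`, lapply(ind_list, function(i) {
    v <- i$frost_free; v[is.na(v)] <- FALSE; v + 0
  }))
  ff <- votes > length(ind_list) / 2
  ff[Reduce(`|`, lapply(ind_list, function(i) is.na(i$frost_free)))] <- NA
  structure(list(P = P, Tbio = Tbio, PET = PET, R = R, frost_free = ff,
                 grid = ind_list[[1]]$grid, period = ind_list[[1]]$period,
                 scenario = ind_list[[1]]$scenario, gcm = "ensemble-median"),
            class = "climate_indicators")
}
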