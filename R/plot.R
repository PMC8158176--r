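# Minimal chart graphics: the triangle frame, an SCS mask, and future
# production density, in base graphics.

#' Plot a safe climatic space mask in the Holdridge triangle
#'
#' Draws the member bins of an SCS mask over the triangle outline, optionally
#' overlaying future production positions (dot size by mass).
#'
#' @param mask an [build_scs()] mask.
#' @param points optional [to_triangle()] positions to overlay.
#' @param production optional mass matrix scaling the overlay dots.
#' @param main plot title.
#' @return Invisibly, `NULL`. Called for its side effect.
#' @export
plot_scs <- function(mask, points = NULL, production = NULL,
                     main = sprintf("Safe climatic space (%s)", mask$sector)) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(-1, 1), xlab = "X", ylab = "Y",
                 main = main, asp = 1)
  nx <- length(mask$xedges) - 1L
  ny <- length(mask$yedges) - 1L
  idx <- which(mask$member, arr.ind = TRUE)
  if (nrow(idx)) {
    graphics::rect(mask$xedges[idx[, 1]], mask$yedges[idx[, 2]],
                   mask$xedges[idx[, 1] + 1L], mask$yedges[idx[, 2] + 1L],
                   col = "#9ecfe8", border = NA)
  }
  # chart outline: the [0,1]^2 (P', R') square maps to the diamond with
  # vertices (0.5, 1), (1, 0), (0.5, -1), (0, 0)
  graphics::polygon(c(0.5, 1, 0.5, 0), c(1, 0, -1, 0), border = "grey30")
  if (!is.null(points)) {
    w <- if (is.null(production)) rep(1, length(points$X)) else
      as.vector(production)
    keep <- is.finite(points$X) & is.finite(w) & w > 0
    cex <- 0.2 + 1.3 * sqrt(w[keep] / max(w[keep]))
    graphics::points(points$X[keep], points$Y[keep], pch = 16, cex = cex,
                     col = grDevices::adjustcolor("#c0392b", 0.35))
  }
  invisible(NULL)
}
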