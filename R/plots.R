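#' Rose plot of track directions
#'
#' Circular histogram of net track directions (0 degrees = toward the
#' posterior pole, drawn to the right), one overlaid polygon per distance
#' band.
#'
#' @param dirhist a bins x bands count matrix from
#'   \code{\link{direction_histogram}}.
#' @param main plot title.
#' @return invisibly, the input matrix.
#' @export
plot_direction_rose <- function(dirhist, main = "Track directions") {
  nb <- nrow(dirhist)
  interval <- 360 / nb
  mids <- (as.numeric(rownames(dirhist)) + interval / 2) * pi / 180
  rmax <- max(dirhist, 1)
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  th <- seq(0, 2 * pi, length.out = 120)
  for (r in pretty(c(0, rmax))[-1])
    graphics::lines(r * cos(th), r * sin(th), col = "grey85")
  cols <- grDevices::hcl.colors(max(ncol(dirhist), 2), "Dark 2")
  for (j in seq_len(ncol(dirhist))) {
    r <- dirhist[, j]
    graphics::polygon(r * cos(mids), r * sin(mids), border = cols[j],
                      col = grDevices::adjustcolor(cols[j], 0.2))
  }
  graphics::legend("topright", legend = paste(colnames(dirhist), "um"),
                   col = cols[seq_len(ncol(dirhist))], lwd = 2, bty = "n")
  graphics::text(rmax, 0, "posterior", pos = 4, xpd = NA, cex = 0.8)
  invisible(dirhist)
}

#' Image plot of a cargo density grid
#'
#' @param density a \code{\link{cargo_density}}.
#' @param geom optionally, the geometry whose cortex outline to overlay.
#' @param main plot title.
#' @return invisibly, the density.
#' @export
plot_cargo_density <- function(density, geom = NULL,
                               main = "Cargo density") {
  graphics::image(density$xc, density$yc, density$counts,
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  asp = 1, xlab = "x (um)", ylab = "y (um)", main = main)
  if (!is.null(geom)) {
    v <- rbind(geom$cortex, geom$cortex[1, ])
    graphics::lines(v[, 1], v[, 2], lwd = 2)
    graphics::points(geom$posterior_pole[1], geom$posterior_pole[2],
                     pch = 19)
  }
  invisible(density)
}

#' Plot a kymograph occupancy matrix
#'
#' @param kymo matrix from \code{\link{render_kymograph}} (arc-length bins
#'   x frames).
#' @param frame_dt frame interval, s.
#' @param bin arc-length bin width, um.
#' @param main plot title.
#' @return invisibly, the matrix.
#' @export
plot_kymograph <- function(kymo, frame_dt = 1.7, bin = 0.5,
                           main = "Cortical kymograph") {
  t <- (seq_len(ncol(kymo)) - 1L) * frame_dt
  s <- (seq_len(nrow(kymo)) - 0.5) * bin
  graphics::image(t, s, t(kymo), col = c("white", "black"),
                  xlab = "time (s)", ylab = "arc length (um)", main = main)
  invisible(kymo)
}
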