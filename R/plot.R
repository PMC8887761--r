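# Base-graphics visualization of a specimen annotation.

LEVEL_COLORS <- c(c = "#d73027", p = "#fc8d59", x = "#fee090",
                  y = "#e0f3f8", a = "#91bfdb", v = "#4575b4")

#' Plot a specimen annotation
#'
#' Draws the CTI boundary, TC/VB contours, isthmus lines, PM segment
#' contours and ramification sites (colored by level; virtual anchors as
#' open symbols) in image coordinates.
#'
#' @param x a `cti_specimen`
#' @param main plot title (defaults to the specimen id)
#' @param ... further arguments passed to [graphics::plot()]
#' @return `x`, invisibly
#' @export
plot.cti_specimen <- function(x, main = x$specimen_id, ...) {
  all_xy <- rbind(x$cti_boundary, x$tc_contour, x$vb_contour,
                  cbind(x$ramifications$x, x$ramifications$y))
  graphics::plot(all_xy, type = "n", asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                 main = main, ...)
  graphics::polygon(x$cti_boundary, border = "grey30", lwd = 2)
  graphics::polygon(x$tc_contour, col = grDevices::adjustcolor("grey60", 0.5),
                    border = NA)
  graphics::polygon(x$vb_contour, col = grDevices::adjustcolor("grey60", 0.5),
                    border = NA)
  for (key in c("ili_line", "ci_line", "psi_line"))
    graphics::lines(x[[key]], lty = 2, col = "grey40")
  for (ct in x$segments$contour)
    graphics::polygon(ct, col = grDevices::adjustcolor("#8c510a", 0.45),
                      border = "#8c510a")
  r <- x$ramifications
  graphics::points(r$x, r$y, pch = ifelse(r$virtual, 1, 21),
                   bg = LEVEL_COLORS[r$level], col = "black", cex = 1.2)
  graphics::legend("topright", legend = names(LEVEL_COLORS), pt.bg = LEVEL_COLORS,
                   pch = 21, cex = 0.8, title = "level", bty = "n")
  invisible(x)
}
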