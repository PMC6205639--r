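#' Plot a point pattern with an optional quadrat-grid overlay
#'
#' Draws the pattern (y axis flipped to match image convention), and when a
#' placement or sample is supplied, overlays the tilted quadrat outlines and
#' highlights the counted points. Intended for visual inspection and
#' documentation; the counting itself never goes through graphics code.
#'
#' @param x a [point_pattern()].
#' @param placement optional [place_grid()] result or [sample_pattern()]
#'   result (the latter also highlights counted points).
#' @param cex point size (default 0.4).
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ppattern <- function(x, placement = NULL, cex = 0.4, ...) {
  bb <- x$bbox
  counted <- NULL
  if (inherits(placement, "quadrat_sample")) {
    counted <- placement$counted
    placement <- placement$placement
  }
  graphics::plot(NA, xlim = c(bb$xmin, bb$xmin + bb$width),
                 ylim = rev(c(bb$ymin, bb$ymin + bb$height)),
                 xlab = "x (px)", ylab = "y (px)", asp = 1, ...)
  graphics::rect(bb$xmin, bb$ymin, bb$xmin + bb$width, bb$ymin + bb$height,
                 border = "blue")
  graphics::points(x$x, x$y, pch = 16, cex = cex,
                   col = if (is.null(counted)) "grey30"
                         else ifelse(counted, "red", "grey60"))
  if (!is.null(placement)) {
    g <- placement$grid
    anchors <- enumerate_quadrats(placement)
    for (k in seq_len(nrow(anchors))) {
      cx <- anchors$gx[k] + c(0, g$t, g$t, 0, 0)
      cy <- anchors$gy[k] + c(0, 0, g$t, g$t, 0)
      img <- .image_frame(cx, cy, placement$bbox, g$theta)
      graphics::lines(img$x, img$y, col = "darkgreen")
    }
  }
  invisible(x)
}
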