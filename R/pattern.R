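#' Rectangular bounding box
#'
#' The tight rectangle enclosing the particle positions. Its area `Bx * By`
#' defines the initial quadrat count `n0 = Bx * By / T^2` of a grid, and
#' cropping to it is the protocol's first step (empty margins waste quadrats).
#'
#' @param width box width `Bx` in pixels (> 0).
#' @param height box height `By` in pixels (> 0).
#' @param xmin,ymin coordinates of the top-left corner (image convention:
#'   y grows downward). Default 0.
#' @return An object of class `"bounding_box"` with fields `xmin`, `ymin`,
#'   `width`, `height` and `area`.
#' @examples
#' bounding_box(640, 480)
#' @export
bounding_box <- function(width, height, xmin = 0, ymin = 0) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1L,
            length(height) == 1L, is.finite(width), is.finite(height))
  if (width <= 0 || height <= 0)
    stop("bounding box must have positive width and height", call. = FALSE)
  structure(
    list(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         width = as.numeric(width), height = as.numeric(height),
         area = as.numeric(width) * as.numeric(height)),
    class = "bounding_box"
  )
}

.check_bbox <- function(bbox) {
  if (!inherits(bbox, "bounding_box"))
    stop("expected a 'bounding_box' object; see bounding_box()", call. = FALSE)
  invisible(bbox)
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("bounding box: %g x %g px at (%g, %g), area %g px^2\n",
              x$width, x$height, x$xmin, x$ymin, x$area))
  invisible(x)
}

#' Planar point pattern with known size
#'
#' A finite set of N zero-extent particles (e.g. annotated head positions) in
#' a bounding box. The true size N equals the number of points and is carried
#' along because the empirical coefficient of error normalizes by it.
#'
#' @param x,y numeric vectors of particle coordinates in pixels.
#' @param bbox a [bounding_box()]; if `NULL`, the tight axis-aligned box of
#'   the points is used (a degenerate or empty pattern gets a 1x1 box).
#' @param check if `TRUE` (default), verify that all points lie inside the
#'   bounding box.
#' @return An object of class `"ppattern"`: list with `x`, `y`, `bbox`, `N`.
#' @examples
#' p <- point_pattern(c(10, 20, 30), c(5, 15, 25), bounding_box(100, 100))
#' p$N
#' @export
point_pattern <- function(x, y, bbox = NULL, check = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("point coordinates must not contain NA", call. = FALSE)
  if (is.null(bbox)) {
    if (length(x) == 0L) {
      bbox <- bounding_box(1, 1)
    } else {
      bbox <- bounding_box(max(diff(range(x)), 1e-9),
                           max(diff(range(y)), 1e-9),
                           xmin = min(x), ymin = min(y))
    }
  }
  .check_bbox(bbox)
  if (check && length(x) > 0L) {
    inside <- x >= bbox$xmin & x <= bbox$xmin + bbox$width &
              y >= bbox$ymin & y <= bbox$ymin + bbox$height
    if (!all(inside))
      stop(sum(!inside), " point(s) fall outside the bounding box",
           call. = FALSE)
  }
  structure(list(x = x, y = y, bbox = bbox, N = length(x)),
            class = "ppattern")
}

.check_pattern <- function(pattern) {
  if (!inherits(pattern, "ppattern"))
    stop("expected a 'ppattern' object; see point_pattern()", call. = FALSE)
  invisible(pattern)
}

#' @export
print.ppattern <- function(x, ...) {
  cat(sprintf("planar point pattern: N = %d points\n", x$N))
  print(x$bbox)
  invisible(x)
}

#' Read / write point patterns as CSV
#'
#' Patterns are exchanged as plain CSV with header `x,y` (pixel units).
#' An optional JSON sidecar (`<file>.json`) stores the bounding box and the
#' true N so a pattern round-trips exactly.
#'
#' @param file path to the CSV file.
#' @param bbox optional [bounding_box()] overriding any sidecar.
#' @return `read_pattern` returns a `"ppattern"`; `write_pattern` returns
#'   `file` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_pattern(rpattern_uniform(10, bounding_box(100, 100), seed = 1), f)
#' read_pattern(f)$N
#' @export
read_pattern <- function(file, bbox = NULL) {
  df <- utils::read.csv(file)
  if (!all(c("x", "y") %in% names(df)))
    stop("pattern CSV must have columns 'x' and 'y'", call. = FALSE)
  sidecar <- paste0(file, ".json")
  if (is.null(bbox) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    bb <- meta$bounding_box
    if (!is.null(bb))
      bbox <- bounding_box(bb$width, bb$height, bb$xmin, bb$ymin)
  }
  point_pattern(df$x, df$y, bbox = bbox)
}

#' @param pattern a `"ppattern"` object.
#' @param sidecar write the JSON metadata sidecar? Default `TRUE`.
#' @rdname read_pattern
#' @export
write_pattern <- function(pattern, file, sidecar = TRUE) {
  .check_pattern(pattern)
  utils::write.csv(data.frame(x = pattern$x, y = pattern$y), file,
                   row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(
      N = pattern$N,
      bounding_box = pattern$bbox[c("xmin", "ymin", "width", "height")]
    )
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(file)
}
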