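#' Quadrat grid parameters
#'
#' A systematic grid of square quadrats of side `t` whose anchors (lower-left
#' corners in the grid's own frame) sit on a square lattice of period `T`
#' (argument `period`), tilted by `theta` degrees with respect to the image
#' x axis. The grid can equivalently be specified through the sampling
#' fraction `f = t^2/T^2` (the fraction of the plane covered by quadrats,
#' hence every particle's inclusion probability) and the initial quadrat
#' count `n0 = Bx*By/T^2` (the expected number of grid tiles over the
#' bounding box), from which
#' \deqn{T = \sqrt{B_x B_y / n_0}, \qquad t = T\sqrt{f}.}
#'
#' Supply either both `t` and `period`, or both `f` and `n0` together with
#' `bbox`. `f = 1` makes the quadrats tile the plane (every particle counted
#' exactly once).
#'
#' @param f sampling fraction, in (0, 1].
#' @param n0 initial number of quadrats (> 0, need not be an integer).
#' @param t quadrat side in pixels (0 < t <= period).
#' @param period grid period T in pixels.
#' @param bbox a [bounding_box()]; required for the \{f, n0\} form.
#' @param theta tilt angle in degrees from the x axis (default 30, a fixed
#'   arbitrary tilt that guards against alignments of quadrat rows with
#'   particle rows).
#' @return An object of class `"quadrat_grid"`: list with `t`, `period`,
#'   `theta`.
#' @examples
#' g <- quadrat_grid(f = 0.04, n0 = 50, bbox = bounding_box(1000, 500))
#' c(g$t, g$period) # 20, 100
#' grid_fraction(g, bounding_box(1000, 500))
#' @export
quadrat_grid <- function(f = NULL, n0 = NULL, t = NULL, period = NULL,
                         bbox = NULL, theta = 30) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  has_ft <- !is.null(t) && !is.null(period)
  has_fn <- !is.null(f) && !is.null(n0)
  if (has_ft == has_fn)
    stop("supply either {t, period} or {f, n0, bbox}, not both or neither",
         call. = FALSE)
  if (has_fn) {
    .check_bbox(bbox)
    stopifnot(is.numeric(f), is.numeric(n0), length(f) == 1L,
              length(n0) == 1L)
    if (!is.finite(f) || f <= 0 || f > 1)
      stop("sampling fraction f must lie in (0, 1]", call. = FALSE)
    if (!is.finite(n0) || n0 <= 0)
      stop("initial quadrat count n0 must be positive", call. = FALSE)
    period <- sqrt(bbox$area / n0)
    t <- period * sqrt(f)
  } else {
    stopifnot(is.numeric(t), is.numeric(period), length(t) == 1L,
              length(period) == 1L)
    if (!is.finite(period) || period <= 0 || !is.finite(t) || t <= 0 ||
        t > period * (1 + 1e-12))
      stop("quadrat side must satisfy 0 < t <= period", call. = FALSE)
    t <- min(t, period)
  }
  structure(list(t = as.numeric(t), period = as.numeric(period),
                 theta = as.numeric(theta)),
            class = "quadrat_grid")
}

.check_grid <- function(grid) {
  if (!inherits(grid, "quadrat_grid"))
    stop("expected a 'quadrat_grid' object; see quadrat_grid()",
         call. = FALSE)
  invisible(grid)
}

#' @export
print.quadrat_grid <- function(x, ...) {
  cat(sprintf(
    "quadrat grid: side t = %g px, period T = %g px (f = %g), tilt %g deg\n",
    x$t, x$period, (x$t / x$period)^2, x$theta))
  invisible(x)
}

#' Sampling fraction of a grid
#'
#' The sampling fraction of a quadrat grid, `f = t^2/T^2`, together with the
#' initial quadrat count with respect to a bounding box, `n0 = Bx*By/T^2`.
#' Exact inverse of the \{f, n0\} constructor form of [quadrat_grid()].
#'
#' @param grid a [quadrat_grid()].
#' @param bbox a [bounding_box()].
#' @return List with components `f` and `n0`.
#' @export
grid_fraction <- function(grid, bbox) {
  .check_grid(grid); .check_bbox(bbox)
  list(f = (grid$t / grid$period)^2, n0 = bbox$area / grid$period^2)
}

# Map image coordinates into the grid frame: translate to the bounding-box
# origin, then rotate by -theta so the grid lattice is axis-aligned.
.grid_frame <- function(x, y, bbox, theta) {
  th <- theta * pi / 180
  dx <- x - bbox$xmin
  dy <- y - bbox$ymin
  list(x = cos(th) * dx + sin(th) * dy,
       y = -sin(th) * dx + cos(th) * dy)
}

# Inverse map: grid frame -> image coordinates.
.image_frame <- function(x, y, bbox, theta) {
  th <- theta * pi / 180
  list(x = bbox$xmin + cos(th) * x - sin(th) * y,
       y = bbox$ymin + sin(th) * x + cos(th) * y)
}

#' Superimpose a grid uniformly at random
#'
#' Draws the grid's uniform-random offset `z` in the fundamental tile
#' J0 = [0, T) x [0, T) (a T x T square in the grid's tilted frame) and binds
#' grid, offset and bounding box into a placement. The uniform offset is what
#' makes the estimator design-unbiased: each particle's inclusion probability
#' is exactly f regardless of the pattern.
#'
#' @param grid a [quadrat_grid()].
#' @param bbox the [bounding_box()] being sampled.
#' @param seed optional integer; when given, the placement is reproducible
#'   and the caller's RNG stream is left untouched.
#' @param z optional explicit offset `c(zx, zy)` in `[0, T)^2`, bypassing the
#'   random draw (used for systematic replication).
#' @return An object of class `"grid_placement"`: list with `grid`, `bbox`,
#'   `z`.
#' @examples
#' g <- quadrat_grid(f = 0.04, n0 = 100, bbox = bounding_box(640, 480))
#' place_grid(g, bounding_box(640, 480), seed = 1)$z
#' @export
place_grid <- function(grid, bbox, seed = NULL, z = NULL) {
  .check_grid(grid); .check_bbox(bbox)
  if (is.null(z)) {
    z <- .with_seed(seed, stats::runif(2, 0, grid$period))
  } else {
    z <- as.numeric(z)
    stopifnot(length(z) == 2L)
    if (any(z < 0) || any(z >= grid$period))
      stop("offset z must lie in [0, T)^2", call. = FALSE)
  }
  structure(list(grid = grid, bbox = bbox, z = z), class = "grid_placement")
}

.check_placement <- function(placement) {
  if (!inherits(placement, "grid_placement"))
    stop("expected a 'grid_placement' object; see place_grid()",
         call. = FALSE)
  invisible(placement)
}

#' @export
print.grid_placement <- function(x, ...) {
  print(x$grid)
  cat(sprintf("offset z = (%.3f, %.3f) in J0 = [0, %g)^2\n",
              x$z[1], x$z[2], x$grid$period))
  invisible(x)
}

#' Enumerate the quadrats that can meet the bounding box
#'
#' Lists the quadrat anchors `z + (i*T, j*T)` (grid-frame coordinates) for
#' all lattice indices whose quadrat could intersect the bounding box. The
#' result is a conservative superset (one extra ring of tiles): empty
#' quadrats contribute nothing to any count, so over-enumeration is harmless,
#' while under-enumeration would bias the estimator.
#'
#' @param placement a [place_grid()] result.
#' @return A data frame with columns `i`, `j` (lattice indices) and `gx`,
#'   `gy` (anchor coordinates in the grid frame).
#' @export
enumerate_quadrats <- function(placement) {
  .check_placement(placement)
  g <- placement$grid; bb <- placement$bbox
  corners <- .grid_frame(
    bb$xmin + c(0, bb$width, 0, bb$width),
    bb$ymin + c(0, 0, bb$height, bb$height),
    bb, g$theta)
  irange <- floor((range(corners$x) - placement$z[1]) / g$period) + c(-1, 1)
  jrange <- floor((range(corners$y) - placement$z[2]) / g$period) + c(-1, 1)
  idx <- expand.grid(i = seq(irange[1], irange[2]),
                     j = seq(jrange[1], jrange[2]))
  data.frame(i = idx$i, j = idx$j,
             gx = placement$z[1] + idx$i * g$period,
             gy = placement$z[2] + idx$j * g$period)
}
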