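#' Synthetic point patterns with exact size
#'
#' Generators for fixed-N planar point patterns spanning the spatial regimes
#' a crowd-counting or ecological image can present: complete spatial
#' randomness (`rpattern_uniform`), a linear density gradient emulating
#' perspective crowding (`rpattern_gradient`), Thomas-like clustering
#' (`rpattern_clustered`), and a jittered rectangular lattice emulating
#' regular spectator rows (`rpattern_lattice`). All generators condition on
#' the size: the pattern has exactly `n` points, every point strictly inside
#' the bounding box, because the empirical coefficient of error normalizes
#' by a known N. Identical arguments and seed reproduce the pattern bit for
#' bit.
#'
#' The default bounding box is 640 x 480 px, a typical annotated-image size.
#'
#' @param n exact number of points (>= 0).
#' @param bbox a [bounding_box()] (default 640 x 480).
#' @param seed optional integer seed; the caller's RNG stream is untouched
#'   when it is given.
#' @return A [point_pattern()] with `N = n`.
#' @name rpattern
NULL

.default_bbox <- function() bounding_box(640, 480)

#' @rdname rpattern
#' @details `rpattern_uniform` draws a binomial process: `n` independent
#'   points uniform on the box.
#' @examples
#' pat <- rpattern_uniform(500, seed = 1)
#' pat$N
#' @export
rpattern_uniform <- function(n, bbox = .default_bbox(), seed = NULL) {
  .check_bbox(bbox)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  .with_seed(seed,
    point_pattern(bbox$xmin + stats::runif(n) * bbox$width,
                  bbox$ymin + stats::runif(n) * bbox$height,
                  bbox = bbox))
}

#' @rdname rpattern
#' @param slope gradient strength in [-2, 2]: the point density is
#'   proportional to `1 + slope * (v - 1/2)` where `v` is the relative depth
#'   `(y - ymin)/By`, so `slope = 2` makes the density vanish at the top edge
#'   and double at the bottom (a perspective crowd seen from above);
#'   `slope = 0` is uniform. Values outside [-2, 2] would make the density
#'   negative somewhere and are rejected.
#' @details `rpattern_gradient` samples the depth coordinate by inverting
#'   the closed-form CDF of the linear density; x stays uniform.
#' @export
rpattern_gradient <- function(n, bbox = .default_bbox(), slope = 1.5,
                              seed = NULL) {
  .check_bbox(bbox)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0,
            is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (abs(slope) > 2)
    stop("|slope| > 2 makes the linear density negative inside the box",
         call. = FALSE)
  .with_seed(seed, {
    u <- stats::runif(n)
    if (slope == 0) {
      v <- u
    } else {
      # invert G(v) = v + slope*(v^2 - v)/2 on [0, 1]
      a <- slope / 2
      b <- 1 - slope / 2
      v <- (-b + sqrt(b^2 + 4 * a * u)) / (2 * a)
    }
    point_pattern(bbox$xmin + stats::runif(n) * bbox$width,
                  bbox$ymin + v * bbox$height,
                  bbox = bbox)
  })
}

#' @rdname rpattern
#' @param parents number of cluster centers (>= 1), placed uniformly.
#' @param sigma isotropic Gaussian dispersion of offspring around their
#'   parent, in pixels (> 0).
#' @details `rpattern_clustered` assigns each of the `n` offspring to a
#'   uniformly chosen parent and displaces it by N(0, sigma^2) per axis;
#'   offspring falling outside the box are redrawn (not clipped), which
#'   preserves exact N at the cost of slightly distorting cluster shape near
#'   the edges.
#' @export
rpattern_clustered <- function(n, bbox = .default_bbox(), parents = 10,
                               sigma = 20, seed = NULL) {
  .check_bbox(bbox)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0,
            is.numeric(parents), parents >= 1, is.numeric(sigma), sigma > 0)
  parents <- as.integer(parents)
  .with_seed(seed, {
    px <- bbox$xmin + stats::runif(parents) * bbox$width
    py <- bbox$ymin + stats::runif(parents) * bbox$height
    assign <- sample.int(parents, n, replace = TRUE)
    x <- numeric(n); y <- numeric(n)
    todo <- seq_len(n)
    while (length(todo) > 0L) {
      x[todo] <- px[assign[todo]] + stats::rnorm(length(todo), 0, sigma)
      y[todo] <- py[assign[todo]] + stats::rnorm(length(todo), 0, sigma)
      inside <- x[todo] > bbox$xmin & x[todo] < bbox$xmin + bbox$width &
                y[todo] > bbox$ymin & y[todo] < bbox$ymin + bbox$height
      todo <- todo[!inside]
    }
    point_pattern(x, y, bbox = bbox)
  })
}

#' @rdname rpattern
#' @param jitter Gaussian jitter sd in pixels (>= 0) applied to each lattice
#'   point; 0 gives perfectly regular rows and columns — the alignment
#'   hazard that motivates tilting the sampling grid.
#' @details `rpattern_lattice` arranges the `n` points on the rectangular
#'   lattice whose row/column counts best fill the box (centered, with half
#'   a spacing of margin), then jitters; jittered points are redrawn until
#'   inside the box.
#' @export
rpattern_lattice <- function(n, bbox = .default_bbox(), jitter = 0,
                             seed = NULL) {
  .check_bbox(bbox)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0,
            is.numeric(jitter), length(jitter) == 1L, jitter >= 0)
  if (n == 0L) return(point_pattern(numeric(0), numeric(0), bbox = bbox))
  ncol <- max(1L, round(sqrt(n * bbox$width / bbox$height)))
  nrow <- ceiling(n / ncol)
  sx <- bbox$width / ncol
  sy <- bbox$height / nrow
  gx <- bbox$xmin + (rep(seq_len(ncol), times = nrow) - 0.5) * sx
  gy <- bbox$ymin + (rep(seq_len(nrow), each = ncol) - 0.5) * sy
  keep <- seq_len(n)   # drop surplus sites from the last row
  x <- gx[keep]; y <- gy[keep]
  if (jitter > 0) {
    jit <- .with_seed(seed, {
      todo <- seq_len(n)
      jx <- x; jy <- y
      while (length(todo) > 0L) {
        jx[todo] <- x[todo] + stats::rnorm(length(todo), 0, jitter)
        jy[todo] <- y[todo] + stats::rnorm(length(todo), 0, jitter)
        inside <- jx[todo] > bbox$xmin & jx[todo] < bbox$xmin + bbox$width &
                  jy[todo] > bbox$ymin & jy[todo] < bbox$ymin + bbox$height
        todo <- todo[!inside]
      }
      list(x = jx, y = jy)
    })
    x <- jit$x; y <- jit$y
  }
  point_pattern(x, y, bbox = bbox)
}
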