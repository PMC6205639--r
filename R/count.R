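#' Locate points in the tiled grid frame
#'
#' Maps image coordinates into the grid frame (inverse tilt about the
#' bounding-box origin), subtracts the placement offset, and identifies for
#' each point the fundamental tile containing it and its local coordinates
#' within that tile.
#'
#' @param placement a [place_grid()] result.
#' @param x,y point coordinates in image pixels.
#' @return Data frame with columns `i`, `j` (tile lattice indices) and
#'   `lx`, `ly` (local coordinates within the tile, in `[0, T)`).
#' @export
locate_points <- function(placement, x, y) {
  .check_placement(placement)
  g <- placement$grid
  q <- .grid_frame(x, y, placement$bbox, g$theta)
  ux <- q$x - placement$z[1]
  uy <- q$y - placement$z[2]
  i <- floor(ux / g$period)
  j <- floor(uy / g$period)
  lx <- ux - i * g$period
  ly <- uy - j * g$period
  # guard against roundoff pushing a local coordinate onto the period
  fix <- lx >= g$period; i[fix] <- i[fix] + 1L; lx[fix] <- 0
  fix <- ly >= g$period; j[fix] <- j[fix] + 1L; ly[fix] <- 0
  data.frame(i = i, j = j, lx = lx, ly = ly)
}

#' Forbidden-line counting decision for a point particle
#'
#' The unbiased-counting-frame rule guarantees that each particle is
#' countable by exactly one quadrat of the (t = T) tiling, and with
#' probability f = t^2/T^2 otherwise. For zero-extent point particles the
#' rule reduces to a half-open boundary convention: a point is counted by
#' the quadrat of its tile iff its local coordinates fall in
#' `[0, t) x [0, t)` — the quadrat's lower-left edges are acceptance edges,
#' the upper-right edges (the extended forbidden lines) exclude.
#'
#' @param lx,ly local coordinates within the fundamental tile, in `[0, T)`.
#' @param t quadrat side.
#' @return Logical vector: counted or not.
#' @export
is_counted <- function(lx, ly, t) {
  lx < t & ly < t
}

# Shared counting core: counts Q and nonempty quadrats n for one or more
# offsets over pre-projected grid-frame coordinates. Every sampling path
# (single placement, Monte Carlo replication) goes through this function so
# the counting rule cannot diverge between them.
.count_at_offsets <- function(qx, qy, period, t, zx, zy, tiles = FALSE) {
  K2 <- length(zx)
  Q <- integer(K2); n <- integer(K2)
  tile_tab <- NULL
  for (k in seq_len(K2)) {
    ux <- qx - zx[k]; uy <- qy - zy[k]
    i <- floor(ux / period); j <- floor(uy / period)
    lx <- ux - i * period; ly <- uy - j * period
    sel <- is_counted(lx, ly, t)
    Q[k] <- sum(sel)
    if (Q[k] > 0L) {
      key <- paste(i[sel], j[sel])
      n[k] <- length(unique(key))
      if (tiles && k == 1L) {
        cnt <- table(key)
        ij <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
        tile_tab <- data.frame(i = as.integer(ij[, 1]),
                               j = as.integer(ij[, 2]),
                               count = as.integer(cnt))
      }
    } else if (tiles && k == 1L) {
      tile_tab <- data.frame(i = integer(0), j = integer(0),
                             count = integer(0))
    }
  }
  list(Q = Q, n = n, tiles = tile_tab)
}

#' Count a point pattern under one grid placement
#'
#' Applies the forbidden-line counting rule to every particle: the total
#' sampled count Q and the number of nonempty quadrats n are the two
#' quantities the protocol inspects. An empty pattern yields Q = 0, n = 0.
#'
#' @param pattern a [point_pattern()].
#' @param placement a [place_grid()] over the same bounding box.
#' @return An object of class `"quadrat_sample"`: list with `Q`, `n`,
#'   per-quadrat `counts` (data frame `i`, `j`, `count`), `counted` (logical
#'   per point), and the `placement`.
#' @examples
#' bb <- bounding_box(640, 480)
#' pat <- rpattern_uniform(500, bb, seed = 1)
#' g <- quadrat_grid(f = 0.04, n0 = 100, bbox = bb)
#' s <- sample_pattern(pat, place_grid(g, bb, seed = 2))
#' c(Q = s$Q, n = s$n)
#' @export
sample_pattern <- function(pattern, placement) {
  .check_pattern(pattern); .check_placement(placement)
  g <- placement$grid
  q <- .grid_frame(pattern$x, pattern$y, pattern$bbox, g$theta)
  res <- .count_at_offsets(q$x, q$y, g$period, g$t,
                           placement$z[1], placement$z[2], tiles = TRUE)
  loc <- locate_points(placement, pattern$x, pattern$y)
  structure(list(Q = res$Q[1], n = res$n[1], counts = res$tiles,
                 counted = is_counted(loc$lx, loc$ly, g$t),
                 placement = placement),
            class = "quadrat_sample")
}

#' @export
print.quadrat_sample <- function(x, ...) {
  cat(sprintf("quadrat sample: Q = %d particles in n = %d nonempty quadrats\n",
              x$Q, x$n))
  invisible(x)
}
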