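test_that("locate_points maps points to tiles and local coordinates", {
  bb <- bounding_box(100, 100)
  g <- quadrat_grid(t = 5, period = 10, theta = 0)
  pl <- place_grid(g, bb, z = c(0, 0))
  loc <- locate_points(pl, 23, 7)
  expect_equal(loc$i, 2)
  expect_equal(loc$j, 0)
  expect_equal(loc$lx, 3)
  expect_equal(loc$ly, 7)

  # a point exactly on a tile corner maps to the lower edge of its own tile
  pl5 <- place_grid(g, bb, z = c(5, 5))
  loc5 <- locate_points(pl5, 5, 5)
  expect_equal(c(loc5$lx, loc5$ly), c(0, 0))
})

test_that("tilted locate round-trips through the forward rotation", {
  bb <- bounding_box(640, 480)
  g <- quadrat_grid(t = 20, period = 60, theta = 30)
  pl <- place_grid(g, bb, seed = 4)
  pat <- rpattern_uniform(100, bb, seed = 8)
  loc <- locate_points(pl, pat$x, pat$y)
  expect_true(all(loc$lx >= 0 & loc$lx < g$period))
  expect_true(all(loc$ly >= 0 & loc$ly < g$period))
  th <- g$theta * pi / 180
  gx <- loc$i * g$period + loc$lx + pl$z[1]
  gy <- loc$j * g$period + loc$ly + pl$z[2]
  expect_equal(bb$xmin + cos(th) * gx - sin(th) * gy, pat$x, tolerance = 1e-9)
  expect_equal(bb$ymin + sin(th) * gx + cos(th) * gy, pat$y, tolerance = 1e-9)
})

test_that("the forbidden-line rule is a half-open quadrat membership test", {
  # with t = T every local position is counted (the quadrats tile the plane)
  expect_true(all(is_counted(runif(100, 0, 10), runif(100, 0, 10), t = 10)))
  # the forbidden (far) edge excludes
  expect_false(is_counted(5, 2, t = 5))
  expect_false(is_counted(2, 5, t = 5))
  # the acceptance (near) edge includes
  expect_true(is_counted(0, 0, t = 5))
})

test_that("inclusion probability is exactly f for any point and tilt", {
  bb <- std_box()
  set.seed(17)
  for (theta in c(0, 30, 61.7)) {
    for (rep in 1:3) {
      x <- runif(1, bb$xmin, bb$xmin + bb$width)
      y <- runif(1, bb$ymin, bb$ymin + bb$height)
      f <- runif(1, 0.02, 0.5)
      g <- quadrat_grid(f = f, n0 = 75, bbox = bb, theta = theta)
      # exhaustive 200x200 offset sweep; per-axis lattice count is within
      # 1/M of t/T, so the product is within ~2*sqrt(f)/M + 1/M^2 of f
      frac <- offset_sweep_fraction(x, y, bb, g, M = 200)
      expect_lt(abs(frac - f), 2 * sqrt(f) / 200 + 1 / 200^2)
    }
  }
})

test_that("counting a pattern returns consistent Q, n and per-quadrat counts", {
  bb <- std_box()
  pat <- rpattern_uniform(800, bb, seed = 2)
  g <- quadrat_grid(f = 0.05, n0 = 100, bbox = bb)
  s <- sample_pattern(pat, place_grid(g, bb, seed = 3))
  expect_identical(s$Q, sum(s$counts$count))
  expect_identical(s$n, nrow(s$counts))
  expect_identical(s$Q, sum(s$counted))
  expect_true(all(s$counts$count >= 1))
  expect_gte(s$Q, s$n)
})

test_that("with t = T every particle is counted exactly once", {
  bb <- std_box()
  g <- quadrat_grid(f = 1, n0 = 64, bbox = bb, theta = 30)
  for (seed in 1:3) {
    pat <- rpattern_uniform(257, bb, seed = seed)
    s <- sample_pattern(pat, place_grid(g, bb, seed = seed + 10))
    expect_identical(s$Q, pat$N)
    expect_equal(estimate_size(s$Q, g), pat$N)
  }
})

test_that("an empty pattern yields Q = 0 and n = 0", {
  bb <- std_box()
  pat <- point_pattern(numeric(0), numeric(0), bb)
  g <- quadrat_grid(f = 0.04, n0 = 100, bbox = bb)
  s <- sample_pattern(pat, place_grid(g, bb, seed = 1))
  expect_identical(s$Q, 0L)
  expect_identical(s$n, 0L)
})

test_that("a single point is counted on a t x t sub-region of offset space", {
  bb <- bounding_box(200, 200)
  g <- quadrat_grid(t = 15, period = 50, theta = 0)
  pat <- point_pattern(77, 123, bb)
  M <- 120
  zg <- (seq_len(M) - 0.5) * g$period / M
  hits <- 0L
  for (zx in zg) {
    pl <- list(grid = g, bbox = bb, z = c(zx, 0))
    class(pl) <- "grid_placement"
    for (zy in zg) {
      pl$z <- c(zx, zy)
      hits <- hits + sample_pattern(pat, pl)$Q
    }
  }
  f <- (g$t / g$period)^2
  expect_lt(abs(hits / M^2 - f), 2 * sqrt(f) / M + 1 / M^2)
})

test_that("counts are invariant to point order and grid-frame translation", {
  bb <- std_box()
  pat <- rpattern_uniform(400, bb, seed = 5)
  g <- quadrat_grid(f = 0.06, n0 = 90, bbox = bb, theta = 30)
  pl <- place_grid(g, bb, seed = 6)
  s <- sample_pattern(pat, pl)

  perm <- sample(pat$N)
  s_perm <- sample_pattern(point_pattern(pat$x[perm], pat$y[perm], bb), pl)
  expect_identical(s_perm$Q, s$Q)
  expect_identical(s_perm$n, s$n)

  # translate pattern and offset by the same grid-frame vector
  th <- g$theta * pi / 180
  d <- c(7.3, 11.9)
  dx <- cos(th) * d[1] - sin(th) * d[2]
  dy <- sin(th) * d[1] + cos(th) * d[2]
  pat2 <- point_pattern(pat$x + dx, pat$y + dy, bb, check = FALSE)
  pl2 <- pl
  pl2$z <- pl$z + d  # same shift in the grid frame (tile relabeling only)
  s2 <- sample_pattern(pat2, pl2)
  expect_identical(s2$Q, s$Q)
  expect_identical(s2$n, s$n)
  expect_identical(sort(s2$counts$count), sort(s$counts$count))
})
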