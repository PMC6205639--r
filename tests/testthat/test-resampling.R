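test_that("systematic offsets form a randomly shifted K x K subgrid of J0", {
  off <- systematic_offsets(64, K = 32, seed = 1)
  expect_equal(nrow(off), 1024)
  expect_true(all(off >= 0 & off < 64))
  expect_false(any(duplicated(off)))
  # projected mod T/K, every offset reduces to the same shift u
  expect_equal(max(abs(diff(off[, "zx"] %% (64 / 32)))), 0, tolerance = 1e-9)
  expect_equal(max(abs(diff(off[, "zy"] %% (64 / 32)))), 0, tolerance = 1e-9)

  off1 <- systematic_offsets(50, K = 1, seed = 2)
  expect_equal(nrow(off1), 1)
  expect_error(systematic_offsets(50, K = 0), "at least 1")
})

test_that("f = 1 gives a zero-variance estimator for every pattern", {
  bb <- std_box()
  g <- quadrat_grid(f = 1, n0 = 80, bbox = bb, theta = 30)
  for (pat in list(rpattern_uniform(300, bb, seed = 1),
                   rpattern_clustered(300, bb, seed = 2))) {
    r <- resample_ce(pat, g, K = 8, seed = 3)
    expect_equal(r$Nhat_k, rep(pat$N, 64))
    expect_identical(r$Var_e, 0)
    expect_identical(r$CE_e, 0)
    expect_equal(exact_mean_oracle(pat, g, M = 50), pat$N)
  }
})

test_that("resampling refuses an empty pattern", {
  bb <- std_box()
  pat <- point_pattern(numeric(0), numeric(0), bb)
  g <- quadrat_grid(f = 0.04, n0 = 100, bbox = bb)
  expect_error(resample_ce(pat, g, K = 8), "undefined")
})

test_that("a single point recovers the Bernoulli closed form", {
  bb <- std_box()
  f <- 0.04
  g <- quadrat_grid(f = f, n0 = 100, bbox = bb, theta = 30)
  pat <- point_pattern(211.5, 137.2, bb)
  r <- resample_ce(pat, g, K = 32, seed = 9)
  # the K x K subgrid captures the point in cx*cy cells with
  # cx, cy in {floor, ceiling}(t*K/T); the empirical CE^2 = p(1-p)/f^2
  # must land between the values at those extremes of p
  m <- g$t * 32 / g$period
  p_rng <- c(floor(m)^2, ceiling(m)^2) / 32^2
  ce2_rng <- range(p_rng * (1 - p_rng) / f^2)
  expect_gte(r$CE2_e, ce2_rng[1])
  expect_lte(r$CE2_e, ce2_rng[2])
  # and the target value (1-f)/f lies in the same bracket
  expect_gte((1 - f) / f, ce2_rng[1])
  expect_lte((1 - f) / f, ce2_rng[2])
})

test_that("the replicate mean is unbiased and mean Q is f*N", {
  bb <- std_box()
  pat <- rpattern_uniform(1120, bb, seed = 4)
  g <- quadrat_grid(f = 0.06, n0 = 100, bbox = bb, theta = 30)
  r <- resample_ce(pat, g, K = 32, seed = 5)
  expect_equal(length(r$Nhat_k), 1024)
  expect_lt(abs(r$E_e / pat$N - 1), 0.02)
  expect_lt(abs(r$mean_Q - 0.06 * pat$N), 3 * 0.06 * r$mc_se)
  expect_equal(r$Var_e, mean((r$Nhat_k - r$E_e)^2))
  expect_equal(r$CE2_e, r$Var_e / pat$N^2)
})

test_that("subgrid and independent designs agree on the mean", {
  bb <- std_box()
  pat <- rpattern_uniform(500, bb, seed = 6)
  g <- quadrat_grid(f = 0.05, n0 = 80, bbox = bb)
  rs <- resample_ce(pat, g, K = 32, seed = 7, method = "subgrid")
  ri <- resample_ce(pat, g, K = 32, seed = 7, method = "independent")
  expect_lt(abs(rs$E_e - pat$N), 3 * rs$mc_se)
  expect_lt(abs(ri$E_e - pat$N), 3 * ri$mc_se)
})

test_that("the exhaustive-offset oracle converges to N", {
  bb <- bounding_box(400, 400)
  g <- quadrat_grid(f = 0.04, n0 = 64, bbox = bb, theta = 0)
  pat <- point_pattern(133.7, 251.2, bb)
  expect_lt(abs(exact_mean_oracle(pat, g, M = 500) - 1), 0.02)

  # cross-validation of the two independent error machineries
  pat2 <- rpattern_uniform(200, bb, seed = 8)
  g2 <- quadrat_grid(f = 0.08, n0 = 50, bbox = bb, theta = 30)
  r <- resample_ce(pat2, g2, K = 32, seed = 9)
  o <- exact_mean_oracle(pat2, g2, M = 300)
  tol <- 3 * r$mc_se + 200 * (2 * sqrt(0.08) + 1 / 300) / (0.08 * 300)
  expect_lt(abs(r$E_e - o), tol)
})

test_that("a sweep row reproduces a direct resampling run", {
  bb <- std_box()
  pats <- list(a = rpattern_uniform(500, bb, seed = 10))
  sw <- ce_sweep(pats, data.frame(f = 0.04, n0 = 100), K = 16, seed = 11)
  expect_equal(nrow(sw), 1)
  g <- quadrat_grid(f = 0.04, n0 = 100, bbox = bb)
  r <- resample_ce(pats$a, g, K = 16,
                   seed = (11 + 7919) %% .Machine$integer.max)
  expect_equal(sw$CE2_e, r$CE2_e)
  expect_equal(sw$mean_Q, r$mean_Q)
  expect_true(sw$ok)
})

test_that("the paper-style 2x3 settings grid yields 6 tidy rows per pattern", {
  bb <- std_box()
  pats <- list(u = rpattern_uniform(1120, bb, seed = 12),
               g = rpattern_gradient(1120, bb, seed = 13))
  settings <- expand.grid(f = c(0.02, 0.04, 0.06), n0 = c(50, 100))
  sw <- ce_sweep(pats, settings, K = 8, seed = 14)
  expect_equal(nrow(sw), 12)
  expect_true(all(sw$ok))
  expect_setequal(names(sw),
                  c("pattern", "N", "f", "n0", "T", "t", "theta", "K",
                    "mean_Q", "mean_n", "E_e", "Var_e", "CE2_e", "CE_e",
                    "ok", "error"))
  # error decreases with f at fixed n0 for each uniform/gradient pattern
  for (id in c("u", "g")) {
    sub <- sw[sw$pattern == id & sw$n0 == 100, ]
    sub <- sub[order(sub$f), ]
    expect_true(all(diff(sub$CE2_e) < 0))
  }
})

test_that("a failing sweep cell is flagged, not fatal", {
  bb <- std_box()
  pats <- list(ok = rpattern_uniform(100, bb, seed = 15),
               bad = point_pattern(numeric(0), numeric(0), bb))
  sw <- ce_sweep(pats, data.frame(f = 0.1, n0 = 50), K = 4, seed = 16)
  expect_equal(sw$ok, c(TRUE, FALSE))
  expect_match(sw$error[2], "undefined")
})
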