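test_that("IDW interpolation is exact at data, symmetric, and convex", {
  one <- data.frame(x = 0, y = 0, value = 5)
  q <- data.frame(x = c(0, 10, -3), y = c(0, 2, 7))
  expect_equal(idw_interpolate(one, q), rep(5, 3))

  two <- data.frame(x = c(-1, 1), y = c(0, 0), value = c(2, 4))
  expect_equal(idw_interpolate(two, data.frame(x = 0, y = 5)), 3)
  expect_equal(idw_interpolate(two, data.frame(x = 1, y = 0)), 4)
  expect_error(idw_interpolate(two[0, ], data.frame(x = 0, y = 0)),
               "no known points")

  set.seed(8)
  known <- data.frame(x = runif(6, 0, 100), y = runif(6, 0, 100),
                      value = runif(6, 1, 9))
  qs <- data.frame(x = runif(40, 0, 100), y = runif(40, 0, 100))
  v <- idw_interpolate(known, qs)
  expect_true(all(v >= min(known$value) - 1e-12 &
                    v <= max(known$value) + 1e-12))
})

test_that("skew-normal draws hit the requested moments", {
  expect_equal(draw_skew_normal(5, 7, 0, skew = 1), rep(7, 5))

  x <- draw_skew_normal(1e5, 10, 2, skew = 1, truncate = FALSE, seed = 2)
  expect_lt(abs(mean(x) - 10), 3 * 2 / sqrt(1e5))

  y <- draw_skew_normal(1e5, 10, 2, skew = 2, truncate = FALSE, seed = 3)
  expect_lt(abs(mean(y) - 10), 4 * 2 / sqrt(1e5))
  expect_equal(sd(y), 2, tolerance = 0.02)
  skewness <- mean(((y - mean(y)) / sd(y))^3)
  expect_gt(skewness, 0.2)

  d1 <- draw_skew_normal(100, 5, 1, seed = 11)
  d2 <- draw_skew_normal(100, 5, 1, seed = 11)
  expect_identical(d1, d2)
  expect_true(all(draw_skew_normal(5000, 0.5, 0.5, seed = 4) >= 0))
})

test_that("an estuary iteration conserves a constant field exactly", {
  grid <- small_grid()
  sites <- data.frame(site_id = c("a", "b"), x = c(100, 900),
                      y = c(100, 300))
  dists <- data.frame(site_id = c("a", "b"), mean = c(4, 4), sd = 0,
                      skew = 1.5)
  total <- estuary_iteration(dists, sites, grid, seed = 1)
  expect_equal(total, 4 * grid$total_area_ha, tolerance = 1e-9)

  one <- estuary_iteration(dists[1, ], sites[1, ], grid, seed = 1)
  expect_equal(one, 4 * grid$total_area_ha, tolerance = 1e-9)

  expect_error(
    estuary_iteration(dists, sites[1, ], grid, seed = 1),
    "no location for site")
})

test_that("iteration totals equal a brute-force enumeration on a 3x3 mask", {
  cell <- 10
  centres <- expand.grid(x = c(5, 15, 25), y = c(5, 15, 25))
  grid <- grid_spec(centres, cell)
  sites <- data.frame(site_id = c("a", "b"), x = c(5, 25), y = c(5, 25))
  vals <- c(a = 2, b = 8)
  dists <- data.frame(site_id = c("a", "b"), mean = unname(vals), sd = 0,
                      skew = 1.5)
  # cell-by-cell hand computation with d^-2 weights
  oracle <- 0
  for (i in seq_len(nrow(centres))) {
    d <- sqrt((centres$x[i] - sites$x)^2 + (centres$y[i] - sites$y)^2)
    v <- if (any(d < 1e-9)) vals[which(d < 1e-9)] else
      sum(vals * d^-2) / sum(d^-2)
    oracle <- oracle + v * cell^2 / 1e4
  }
  expect_equal(estuary_iteration(dists, sites, grid, seed = 1),
               unname(oracle), tolerance = 1e-12)
})

test_that("Monte-Carlo estimates are deterministic given a seed, exact at sd 0", {
  grid <- small_grid()
  sites <- data.frame(site_id = c("a", "b"), x = c(100, 900), y = c(100, 300))
  flat <- data.frame(site_id = c("a", "b"), mean = c(3, 7), sd = 0,
                     skew = 1.5)
  est <- estuary_estimate(flat, sites, grid, n_iterations = 5, seed = 9)
  expect_equal(est$total_se, 0)
  expect_equal(est$total_mean,
               estuary_iteration(flat, sites, grid, seed = 1))
  expect_equal(est$areal_mean, est$total_mean / grid$total_area_ha)

  noisy <- transform(flat, sd = c(1, 2))
  e1 <- estuary_estimate(noisy, sites, grid, n_iterations = 20, seed = 3)
  e2 <- estuary_estimate(noisy, sites, grid, n_iterations = 20, seed = 3)
  expect_identical(e1$totals, e2$totals)
  expect_error(estuary_estimate(flat, sites, grid, n_iterations = 1),
               "n_iterations")
})

test_that("refining a rectangular mask leaves the deterministic total stable", {
  sites <- data.frame(site_id = c("a", "b", "c"),
                      x = c(100, 600, 1100), y = c(50, 350, 150))
  dists <- data.frame(site_id = c("a", "b", "c"), mean = c(2, 9, 5),
                      sd = 0, skew = 1.5)
  coarse <- make_mask(30, 10, cell_size = 40, shape = "rectangle")
  fine <- make_mask(60, 20, cell_size = 20, shape = "rectangle")
  expect_equal(coarse$total_area_ha, fine$total_area_ha)
  t_coarse <- estuary_iteration(dists, sites, coarse, seed = 1)
  t_fine <- estuary_iteration(dists, sites, fine, seed = 1)
  expect_lt(abs(t_fine - t_coarse) / t_coarse, 0.005)
})

test_that("aboveground stand N is the composition-weighted species content", {
  expect_equal(aboveground_n_stock(c(A_germinans = 1), 100), 0.26)
  expect_equal(aboveground_n_stock(c(A_germinans = 0.5, L_racemosa = 0.5),
                                   100), 0.2085)
  expect_equal(aboveground_n_stock(c(R_mangle = 1), 0), 0)
  # unknown species fall back to the non-mangrove content
  expect_equal(aboveground_n_stock(c(Conocarpus = 1), 100), 0.31)
  expect_error(aboveground_n_stock(c(A_germinans = 0.6), 100), "sum to 1")
})
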