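test_that("the utilization surface is a proper density on the grid", {
  set.seed(81)
  pts <- data.frame(x_km = rnorm(10000), y_km = rnorm(10000))
  s <- fit_kud(pts, bandwidth = 0.3)
  expect_lt(abs(sum(s$z) * s$cell_area - 1), 1e-6)
  expect_true(all(s$z >= 0))
  expect_identical(s$z, fit_kud(pts, bandwidth = 0.3)$z)  # deterministic
})

test_that("a tight cluster reproduces the analytic Gaussian kernel", {
  pts <- data.frame(x_km = rep(0, 10), y_km = rep(0, 10))
  s <- fit_kud(pts, bandwidth = 1)
  analytic <- outer(s$x, s$y, function(x, y) dnorm(x) * dnorm(y))
  expect_lt(max(abs(s$z - analytic)) / max(analytic), 0.02)
  expect_error(fit_kud(pts, bandwidth = "reference"), "zero variance")
  expect_error(fit_kud(pts[1:3, ]), "at least 5")
})

test_that("isopleth area matches the bivariate normal closed form", {
  pts <- data.frame(x_km = rep(0, 5), y_km = rep(0, 5))
  s <- fit_kud(pts, bandwidth = 1)
  # 90% of a circular Gaussian lies within radius sqrt(2 log 10):
  # area = 2 pi log(10) ~ 14.47 km^2
  expect_lt(abs(isopleth_area(s, 0.90) / (2 * pi * log(10)) - 1), 0.02)
  # monotone in level
  expect_gt(isopleth_area(s, 0.99), isopleth_area(s, 0.90))
  # stable under grid refinement
  s2 <- fit_kud(pts, bandwidth = 1, grid_n = 800)
  expect_lt(abs(isopleth_area(s2, 0.9) / isopleth_area(s, 0.9) - 1), 0.01)
  # unreachable mass errors usefully
  s3 <- fit_kud(pts, bandwidth = 1, pad_factor = 0.5)
  expect_error(isopleth_area(s3, 0.95), "pad")
})

test_that("two disjoint modes double the isopleth area", {
  pts <- data.frame(x_km = c(rep(0, 5), rep(50, 5)),
                    y_km = rep(0, 10))
  s <- fit_kud(pts, bandwidth = 1, grid_n = 800)
  expect_lt(abs(isopleth_area(s, 0.9) / (2 * 2 * pi * log(10)) - 1), 0.03)
})

test_that("area scales quadratically under coordinate scaling", {
  set.seed(82)
  pts <- data.frame(x_km = rnorm(300, sd = 2), y_km = rnorm(300, sd = 2))
  a1 <- isopleth_area(fit_kud(pts, bandwidth = 1), 0.9)
  a2 <- isopleth_area(fit_kud(pts * 2, bandwidth = 2), 0.9)
  expect_lt(abs(a2 / (4 * a1) - 1), 0.02)
})

test_that("density estimates divide the abundance posterior draw by draw", {
  expect_equal(round(unname(density_estimate(208, 240.2)$summary["D_median"]), 2),
               0.87)
  expect_equal(round(unname(density_estimate(276, 1508.8)$summary["D_median"]), 2),
               0.18)
  N <- c(100, 200, 300)
  d <- density_estimate(N, 100)
  expect_identical(d$D_draws, N / 100)
  expect_identical(d$D_draws * d$area_km2, d$N_draws)
  expect_equal(unname(density_estimate(rep(42, 10), 42)$summary["D_median"]), 1)
  expect_error(density_estimate(100, 0), "positive")
  expect_error(density_estimate(100, -3), "positive")
})

test_that("early wet-season areas are imputed from the 2013-2019 mean", {
  areas <- setNames(rep(100, 7), 2013:2019)
  expect_equal(as.numeric(impute_wet_area(areas)), 100)
  areas2 <- setNames(c(70, 80, 90, 100, 110, 120, 130), 2013:2019)
  im <- impute_wet_area(areas2)
  expect_equal(as.numeric(im), 100)
  expect_equal(attr(im, "area_source"), "imputed_mean_wet_2013_2019")
  expect_error(impute_wet_area(areas2[-4]), "2016")
})

test_that("isopleth rings trace the level-set boundary", {
  pts <- data.frame(x_km = rep(0, 5), y_km = rep(0, 5))
  s <- fit_kud(pts, bandwidth = 1)
  rings <- isopleth_rings(s, 0.9)
  expect_gte(length(rings), 1)
  r <- sqrt(rings[[1]]$x^2 + rings[[1]]$y^2)
  expect_lt(max(abs(r - sqrt(2 * log(10)))), 0.1)
})
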