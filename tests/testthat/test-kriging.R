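test_that("kriging weights sum to one and degenerate cases close", {
  m <- variogram_model(nugget = 0.1, psill = 0.9, range = 30)
  s <- toy_field_samples(n = 60, extent = 200, seed = 2)
  targets <- tibble::tibble(x = runif(20, 0, 200), y = runif(20, 0, 200))
  eng <- fbgeo:::krige_engine(m, s, as.matrix(targets), neighborhood = 16)
  expect_true(all(abs(eng$weight_sum - 1) < 1e-10))
  # single neighbour: estimate equals that neighbour's value
  one <- ordinary_kriging(m, s, targets[1, ], neighborhood = 1)
  nearest <- s[which.min((s$x - targets$x[1])^2 + (s$y - targets$y[1])^2), ]
  expect_equal(one$estimate, nearest$value)
  # pure nugget: equal weights, neighbourhood mean
  mn <- variogram_model(nugget = 1, psill = 0, range = 30)
  pn <- ordinary_kriging(mn, s[1:10, ], targets[1, ], neighborhood = 10)
  expect_equal(pn$estimate, mean(s$value[1:10]), tolerance = 1e-10)
})

test_that("kriging interpolates exactly at data locations", {
  s <- toy_field_samples(n = 40, extent = 150, nugget = 0, psill = 1,
                         eff_range = 60, seed = 4)
  m <- variogram_model(nugget = 0, psill = 1, range = 20)
  at_data <- ordinary_kriging(m, s, s[3:5, c("x", "y")], neighborhood = 20)
  expect_equal(at_data$estimate, s$value[3:5], tolerance = 1e-8)
  expect_true(all(at_data$kriging_variance < 1e-8))
  away <- ordinary_kriging(m, s,
                           tibble::tibble(x = 75.123, y = 80.456),
                           neighborhood = 20)
  expect_gt(away$kriging_variance, 0)
})

test_that("small-instance kriging equals the direct GLS oracle", {
  m <- variogram_model(nugget = 0.15, psill = 0.85, range = 25, nu = 0.5)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(4:8, 1)
      s <- tibble::tibble(x = runif(n, 0, 100), y = runif(n, 0, 100),
                          value = rnorm(n))
      tg <- c(runif(1, 0, 100), runif(1, 0, 100))
    })
    got <- ordinary_kriging(m, s, tibble::tibble(x = tg[1], y = tg[2]),
                            neighborhood = nrow(s))
    want <- ok_oracle(m, s, tg)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-8)
    expect_equal(got$kriging_variance, want$variance, tolerance = 1e-8)
  }
})

test_that("duplicate coordinates without nugget raise a singular-system error", {
  s <- tibble::tibble(x = c(10, 10, 50), y = c(10, 10, 40),
                      value = c(1, 2, 3))
  m <- variogram_model(nugget = 0, psill = 1, range = 20)
  expect_error(
    ordinary_kriging(m, s, tibble::tibble(x = 30, y = 30), neighborhood = 3),
    class = "fbgeo_error_singular_system")
  # a nugget regularizes the same system
  mn <- variogram_model(nugget = 0.2, psill = 0.8, range = 20)
  expect_no_error(
    ordinary_kriging(mn, s, tibble::tibble(x = 30, y = 30), neighborhood = 3))
})

test_that("LOO cross-validation closes on degenerate and scaled models", {
  # constant field with nugget: every prediction is the constant, SSPE 0
  s <- tibble::tibble(x = runif(25, 0, 100), y = runif(25, 0, 100), value = 7)
  m <- variogram_model(nugget = 0.5, psill = 0.5, range = 30)
  cv <- loo_cross_validation(m, s)
  expect_true(all(abs(cv$sites$predicted - 7) < 1e-10))
  expect_true(all(cv$sites$sspe < 1e-12))
  # inflating the sill by 4 scales every SSPE by exactly 1/4
  s2 <- toy_field_samples(n = 80, extent = 300, seed = 6)
  base <- variogram_model(nugget = 0.2, psill = 0.8, range = 28)
  infl <- variogram_model(nugget = 0.8, psill = 3.2, range = 28)
  cv_base <- loo_cross_validation(base, s2)
  cv_infl <- loo_cross_validation(infl, s2)
  expect_equal(cv_infl$sites$sspe, cv_base$sites$sspe / 4, tolerance = 1e-10)
  expect_equal(cv_infl$mean_sspe, cv_base$mean_sspe / 4, tolerance = 1e-10)
})

test_that("SSPE of a well-specified model is approximately chi-squared(1)", {
  # a single larger field: mean near 1, median near the chi2(1) median
  s <- toy_field_samples(n = 400, extent = 500, nugget = 0.2, psill = 0.8,
                         eff_range = 84, seed = 9)
  m <- variogram_model(nugget = 0.2, psill = 0.8,
                       range = matern_range_from_effective(84, 0.5))
  cv <- loo_cross_validation(m, s, neighborhood = 64)
  expect_lt(abs(cv$mean_sspe - 1), 0.2)
  expect_lt(abs(cv$median_sspe - qchisq(0.5, 1)), 0.15)
})

test_that("gridded kriging honours resolution and reproduces data nodes", {
  s <- toy_field_samples(n = 50, extent = 100, seed = 12)
  m <- variogram_model(nugget = 0.1, psill = 0.9, range = 25)
  g1 <- krige_grid(m, s, bbox = c(0, 96, 0, 96), resolution_km = 16,
                   neighborhood = 16)
  g2 <- krige_grid(m, s, bbox = c(0, 96, 0, 96), resolution_km = 8,
                   neighborhood = 16)
  expect_equal(nrow(g1), 7^2)
  expect_equal(nrow(g2), 13^2)  # halving the spacing ~quadruples the nodes
  # a node placed exactly on a sample with zero nugget returns the sample
  m0 <- variogram_model(nugget = 0, psill = 1, range = 25)
  node <- krige_grid(m0, s, bbox = c(s$x[1], s$x[1], s$y[1], s$y[1]),
                     resolution_km = 16, neighborhood = 10)
  expect_equal(node$estimate, s$value[1], tolerance = 1e-8)
})
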