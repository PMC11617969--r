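test_that("empirical semivariogram reproduces closed-form cases", {
  # constant field: zero semivariance at every lag
  set.seed(31)
  s <- data.frame(x = stats::runif(20), y = stats::runif(20), value = 5)
  emp <- empirical_semivariogram(s, n_lags = 6)
  expect_true(all(emp$gamma == 0))

  # two points, values 0 and 2: single pair, gamma = (2^2)/2 = 2
  two <- data.frame(x = c(0, 3), y = c(0, 4), value = c(0, 2))
  emp2 <- empirical_semivariogram(two, n_lags = 1, max_lag = 5)
  expect_equal(nrow(emp2), 1)
  expect_equal(emp2$gamma, 2)
  expect_equal(emp2$n_pairs, 1L)

  expect_error(empirical_semivariogram(
    data.frame(x = rep(1, 12), y = rep(2, 12), value = 1:12)), "coincident")
})

test_that("white noise has a flat semivariogram at the noise variance", {
  set.seed(32)
  n <- 500; sigma2 <- 4
  s <- data.frame(x = stats::runif(n, 0, 100), y = stats::runif(n, 0, 100),
                  value = stats::rnorm(n, sd = sqrt(sigma2)))
  emp <- empirical_semivariogram(s, n_lags = 8)
  expect_true(all(abs(emp$gamma - sigma2) / sigma2 < 0.2))
  expect_equal(mean(emp$gamma), sigma2, tolerance = 0.05)
})

test_that("variogram fitting recovers noise-free generating parameters", {
  true <- list(family = "spherical", nugget = 0.3, psill = 1.2, range = 40)
  lags <- seq(2, 80, length.out = 14)
  emp <- tibble::tibble(
    lag = lags,
    gamma = parkzoning:::.vgm_gamma(lags, true$family, true$nugget,
                                    true$psill, true$range),
    n_pairs = rep(50L, length(lags)))
  fit <- fit_variogram(emp, family = "spherical")
  expect_lt(abs(fit$nugget - true$nugget) / true$nugget, 0.01)
  expect_lt(abs(fit$psill - true$psill) / true$psill, 0.01)
  expect_lt(abs(fit$range - true$range) / true$range, 0.01)

  # flat empirical curve: pure nugget, vanishing partial sill
  flat <- tibble::tibble(lag = lags, gamma = 0.7, n_pairs = 30L)
  ffit <- fit_variogram(flat)
  expect_equal(ffit$nugget, 0.7, tolerance = 0.01)
  expect_lt(ffit$psill, 0.01)

  # scaling values by 10 scales variances by 100 and leaves the range alone
  emp10 <- emp; emp10$gamma <- emp$gamma * 100
  fit10 <- fit_variogram(emp10)
  expect_equal(fit10$nugget, 100 * fit$nugget, tolerance = 0.02 * 100 * fit$nugget + 1e-8)
  expect_equal(fit10$psill, 100 * fit$psill, tolerance = 0.02 * 100 * fit$psill)
  expect_equal(fit10$range, fit$range, tolerance = 0.02 * fit$range)
})

test_that("ordinary kriging weights sum to one and honor exactness", {
  model <- structure(list(family = "spherical", nugget = 0, psill = 2,
                          range = 50, fallback = FALSE), class = "variogram_model")
  set.seed(33)
  for (i in 1:10) {
    coords <- cbind(stats::runif(12, 0, 100), stats::runif(12, 0, 100))
    target <- stats::runif(2, 0, 100)
    w <- ok_weights(coords, target, model)
    expect_equal(sum(w$weights), 1, tolerance = 1e-10)
  }
  # prediction at a sample location with zero nugget returns the sample
  coords <- cbind(c(10, 40, 70, 20), c(10, 60, 30, 80))
  vals <- c(1.5, -2, 0.7, 3.2)
  s <- data.frame(x = coords[, 1], y = coords[, 2], value = vals)
  target <- park_raster(matrix(0, 1, 1), cell_size = 1,
                        xll = 10 - 0.5, yll = 10 - 0.5)  # center (10, 10)
  surf <- krige(s, model, target, neighborhood = 4)
  expect_equal(surf$values[1, 1], 1.5, tolerance = 1e-8)
})

test_that("kriging symmetry and pure-nugget limits hold", {
  model <- structure(list(family = "exponential", nugget = 0.1, psill = 1,
                          range = 30, fallback = FALSE), class = "variogram_model")
  # midpoint of two equal-valued samples predicts that value
  s <- data.frame(x = c(0, 20), y = c(0, 0), value = c(3, 3))
  target <- park_raster(matrix(0, 1, 1), cell_size = 1, xll = 9.5, yll = -0.5)
  expect_equal(krige(s, model, target, neighborhood = 2)$values[1, 1], 3,
               tolerance = 1e-10)

  # pure nugget: prediction is the arithmetic neighborhood mean
  nug <- structure(list(family = "spherical", nugget = 1, psill = 0,
                        range = 10, fallback = FALSE), class = "variogram_model")
  set.seed(34)
  s2 <- data.frame(x = stats::runif(8, 0, 50), y = stats::runif(8, 0, 50),
                   value = stats::rnorm(8))
  t2 <- park_raster(matrix(0, 1, 1), cell_size = 1, xll = 24.5, yll = 24.5)
  expect_equal(krige(s2, nug, t2, neighborhood = 8)$values[1, 1],
               mean(s2$value), tolerance = 1e-10)
})

test_that("isotropic kriging predictions are rotation and translation invariant", {
  model <- structure(list(family = "spherical", nugget = 0.2, psill = 1.5,
                          range = 40, fallback = FALSE), class = "variogram_model")
  set.seed(35)
  s <- data.frame(x = stats::runif(15, 0, 60), y = stats::runif(15, 0, 60),
                  value = stats::rnorm(15))
  target <- c(25, 30)
  base <- ok_weights(cbind(s$x, s$y), target, model)$weights
  theta <- 0.7; shift <- c(100, -40)
  rot <- function(p) cbind(cos(theta) * p[, 1] - sin(theta) * p[, 2] + shift[1],
                           sin(theta) * p[, 1] + cos(theta) * p[, 2] + shift[2])
  moved <- ok_weights(rot(cbind(s$x, s$y)), as.numeric(rot(rbind(target))), model)$weights
  expect_equal(moved, base, tolerance = 1e-8)
})
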