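test_that("the empirical semivariogram matches hand-binned estimates", {
  co <- cbind(c(0, 1, 2), 0)
  emp <- empirical_semivariogram(co, c(0, 1, 0), lag_width = 1, max_dist = 2)
  expect_equal(emp$gamma, c(0.5, 0))     # bins (0,1], (1,2]
  expect_equal(emp$n_pairs, c(2, 1))
  z <- rep(3, 10)
  set.seed(61)
  xy <- cbind(runif(10), runif(10))
  empc <- empirical_semivariogram(xy, z)
  expect_true(all(empc$gamma[empc$n_pairs > 0] == 0))
})

test_that("pair bookkeeping accounts for every pair within reach", {
  set.seed(62)
  xy <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  z <- rnorm(40)
  md <- 4
  emp <- empirical_semivariogram(xy, z, lag_width = 0.5, max_dist = md)
  d <- as.numeric(dist(xy))
  expect_equal(sum(emp$n_pairs), sum(d <= md))
  # empty bins are reported, not dropped
  sparse <- cbind(c(0, 0.1, 10), 0)
  es <- empirical_semivariogram(sparse, c(1, 2, 3), lag_width = 1, max_dist = 10)
  expect_true(any(es$n_pairs == 0))
  expect_true(all(is.na(es$gamma[es$n_pairs == 0])))
})

test_that("theoretical variogram families obey their closed forms", {
  sph <- variogram_model("spherical", nugget = 0.2, psill = 1, range = 4)
  expect_equal(model_gamma(sph, 0), 0)
  expect_equal(model_gamma(sph, 4), 1.2)
  expect_equal(model_gamma(sph, 10), 1.2)
  expc <- variogram_model("exponential", nugget = 0, psill = 1, range = 2)
  expect_equal(model_gamma(expc, 2), 1 - exp(-3))
  gau <- variogram_model("gaussian", nugget = 0, psill = 2, range = 3)
  expect_equal(model_gamma(gau, 3), 2 * (1 - exp(-3)))
  expect_error(model_gamma(sph, -1), "nonnegative")
  # monotone nondecreasing on a parameter grid
  h <- seq(0, 20, by = 0.1)
  for (ty in c("spherical", "exponential", "gaussian"))
    for (c0 in c(0, 0.5)) for (a in c(1, 5, 15)) {
      g <- model_gamma(variogram_model(ty, c0, 1.3, a), h)
      expect_true(all(diff(g) > -1e-12))
    }
})

test_that("weighted least squares recovers parameters from an exact model curve", {
  true <- variogram_model("spherical", nugget = 0.1, psill = 0.9, range = 6)
  emp <- data.frame(lag = seq(0.5, 12, by = 0.5))
  emp$gamma <- model_gamma(true, emp$lag)
  emp$n_pairs <- 50
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$nugget, 0.1, tolerance = 1e-3)
  expect_equal(fit$psill, 0.9, tolerance = 1e-3)
  expect_equal(fit$range, 6, tolerance = 1e-3)
  expect_true(attr(fit, "converged"))
})

test_that("white noise yields a nugget-dominated fit", {
  set.seed(63)
  ok <- vapply(1:10, function(i) {
    xy <- cbind(runif(200, 0, 35), runif(200, 0, 25))
    emp <- empirical_semivariogram(xy, rnorm(200))
    fit <- fit_variogram(emp, "exponential")
    fit$psill / (fit$nugget + fit$psill) < 0.3
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("a flat empirical curve is flagged as unidentifiable", {
  emp <- data.frame(lag = 1:6, gamma = rep(2, 6), n_pairs = 10)
  fit <- fit_variogram(emp, "spherical")
  expect_false(attr(fit, "converged"))
  expect_match(attr(fit, "note"), "unidentifiable")
  expect_error(fit_variogram(emp[1:2, ], "spherical"), "3 nonempty lags")
})

test_that("variogram ranges are recovered from simulated fields", {
  pts <- generate_nested_design(seed = 71)
  co <- cbind(pts$x, pts$y)
  set.seed(72)
  ranges <- vapply(1:12, function(i) {
    env <- simulate_environment(pts, field_params(topo_trend_sd = 0),
                                seed = NULL)
    fit_variogram(empirical_semivariogram(co, env$topography),
                  "exponential")$range
  }, numeric(1))
  expect_gte(median(ranges), 3)   # within +/-40% of the simulated 5 m
  expect_lte(median(ranges), 7)
})

test_that("ordinary kriging interpolates exactly and honours unbiasedness", {
  set.seed(64)
  xy <- cbind(runif(12, 0, 10), runif(12, 0, 10))
  z <- rnorm(12)
  m <- variogram_model("exponential", nugget = 0, psill = 1, range = 4)
  at_datum <- ordinary_kriging(xy, z, m, xy[3, , drop = FALSE], k = 5)
  expect_equal(at_datum$prediction, z[3], tolerance = 1e-10)
  expect_equal(at_datum$variance, 0, tolerance = 1e-10)
  const <- ordinary_kriging(xy, rep(7, 12), m,
                            cbind(runif(6, 0, 10), runif(6, 0, 10)), k = 4)
  expect_equal(const$prediction, rep(7, 6), tolerance = 1e-10)
  wts <- attr(const, "weights")
  for (w in wts) expect_equal(sum(w$weights), 1, tolerance = 1e-10)
  expect_true(all(const$variance >= -1e-10))
})

test_that("kriging weights match a dense solve on three data points", {
  co <- cbind(c(0, 4, 1), c(0, 0, 3))
  z <- c(1.2, -0.5, 2.0)
  m <- variogram_model("spherical", nugget = 0.05, psill = 1, range = 5)
  target <- cbind(1.5, 1.0)
  res <- ordinary_kriging(co, z, m, target, k = 3)
  oracle <- oracle_kriging(co, z, m, c(1.5, 1.0))
  w <- attr(res, "weights")[[1]]
  expect_equal(w$weights[order(w$neighbours)], oracle$weights,
               tolerance = 1e-10)
  expect_equal(res$prediction, oracle$prediction, tolerance = 1e-10)
  expect_equal(res$variance, oracle$variance, tolerance = 1e-10)
})

test_that("sectored search balances neighbours across quadrants", {
  # five closest points all east of the target; four-sector search must
  # reach into the other quadrants
  co <- rbind(cbind(1:5 / 10 + 0.1, 0.01), c(-1, 0), c(0, 1), c(0, -1))
  z <- rnorm(8)
  m <- variogram_model("exponential", nugget = 0.1, psill = 1, range = 2)
  plain <- attr(ordinary_kriging(co, z, m, cbind(0, 0), k = 5,
                                 n_sectors = 1), "weights")[[1]]
  sect <- attr(ordinary_kriging(co, z, m, cbind(0, 0), k = 5,
                                n_sectors = 4), "weights")[[1]]
  expect_true(all(plain$neighbours %in% 1:5))
  expect_true(all(6:8 %in% sect$neighbours))
  expect_equal(sum(sect$weights), 1, tolerance = 1e-10)
})

test_that("cross-validation selects the generating model family more often than not", {
  expect_equal(loo_cross_validation(
    cbind(c(0, 1, 2), 0), c(0, 1, 0),
    variogram_model("spherical", 0.1, 1, 2), k = 2)$selected, 1)
  set.seed(65)
  wins <- vapply(1:8, function(i) {
    xy <- cbind(runif(120, 0, 35), runif(120, 0, 25))
    z <- traitscape:::.grf_unit(xy, 5, 0.05, 1)[, 1]
    emp <- empirical_semivariogram(xy, z)
    fits <- lapply(c("exponential", "spherical", "gaussian"), function(ty)
      fit_variogram(emp, ty))
    names(fits) <- c("exponential", "spherical", "gaussian")
    cv <- loo_cross_validation(xy, z, fits, k = 5)
    expect_equal(unname(cv$rmse[cv$selected]), min(cv$rmse))
    names(cv$rmse)[cv$selected] == "exponential"
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})
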