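test_that("environment preprocessing transforms and filters collinear variables", {
  set.seed(51)
  x <- rnorm(50)
  env <- data.frame(a = x, b = x + rnorm(50, sd = 1e-6), c = rnorm(50))
  out <- preprocess_environment(env)
  expect_equal(ncol(out), 2)
  expect_length(attr(out, "dropped"), 1)
  expect_true(attr(out, "dropped") %in% c("a", "b"))
  out2 <- preprocess_environment(env, corr_threshold = 1)
  expect_equal(ncol(out2), 3)
  env$zeros <- c(0, abs(rnorm(49)))
  expect_error(preprocess_environment(env, ln_vars = "zeros"), "ln_eps")
  ok <- preprocess_environment(env, ln_vars = "zeros", ln_eps = 1,
                               corr_threshold = 1)
  expect_equal(ok$zeros, log(env$zeros + 1))
  expect_error(preprocess_environment(env, sqrt_vars = "missing"), "unknown")
})

test_that("the collinearity drop agrees with exhaustive search on three variables", {
  set.seed(52)
  n <- 200
  u <- rnorm(n)
  env <- data.frame(a = u, b = 0.9 * u + sqrt(1 - 0.81) * rnorm(n))
  env$c <- 0.25 * scale(u)[, 1] + sqrt(1 - 0.0625) * rnorm(n)
  r <- abs(cor(env))
  expect_gt(r["a", "b"], 0.6)
  out <- preprocess_environment(env)
  expect_equal(ncol(out), 2)
  kept <- colnames(out)
  # exhaustive oracle: among single drops resolving the violation, the one
  # minimising the largest remaining correlation
  options_ <- list(c("a", "c"), c("b", "c"))
  maxr <- vapply(options_, function(kp) {
    rr <- abs(cor(env[, kp])); max(rr[upper.tri(rr)])
  }, numeric(1))
  expect_setequal(kept, options_[[which.min(maxr)]])
})

test_that("sequential OLS reproduces exact fits and hand oracles", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  fit <- ols_sequential(2 * x, data.frame(x = x))
  expect_equal(unname(fit$coefficients["x"]), 2)
  expect_equal(fit$adj_r_squared, 1)
  expect_equal(fit$residual_ss, 0, tolerance = 1e-20)
  set.seed(53)
  X <- data.frame(a = rnorm(8), b = rnorm(8))
  y <- rnorm(8)
  fit2 <- ols_sequential(y, X)
  Xc <- cbind(1, sweep(as.matrix(X), 2, colMeans(as.matrix(X))))
  beta <- solve(t(Xc) %*% Xc) %*% t(Xc) %*% y
  expect_equal(unname(fit2$coefficients), unname(beta[-1, 1]), tolerance = 1e-10)
  expect_equal(fit2$total_ss, sum((y - mean(y))^2), tolerance = 1e-10)
  # sequential SS by explicit nested projections
  p1 <- lm(y ~ X$a); p2 <- lm(y ~ X$a + X$b)
  expect_equal(unname(fit2$sequential_ss),
               c(sum((fitted(p1) - mean(y))^2),
                 sum((fitted(p2) - fitted(p1))^2)), tolerance = 1e-10)
  expect_equal(sum(fit2$sequential_ss) + fit2$residual_ss, fit2$total_ss,
               tolerance = 1e-8)
})

test_that("sequential SS is order-invariant for orthogonal predictors and centring-invariant", {
  set.seed(54)
  # orthogonalise against the intercept too, so the columns stay orthogonal
  # after internal centring
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(60), 20, 3))))[, -1]
  X <- data.frame(a = Q[, 1], b = Q[, 2], c = Q[, 3])
  y <- rnorm(20)
  f1 <- ols_sequential(y, X, c("a", "b", "c"))
  f2 <- ols_sequential(y, X, c("c", "a", "b"))
  expect_equal(f1$sequential_ss[c("a", "b", "c")],
               f2$sequential_ss[c("a", "b", "c")], tolerance = 1e-10)
  # shifting predictors changes nothing
  Xs <- X; Xs$a <- Xs$a + 100; Xs$b <- Xs$b - 3
  f3 <- ols_sequential(y, Xs, c("a", "b", "c"))
  expect_equal(f1$sequential_ss, f3$sequential_ss, tolerance = 1e-8)
  expect_equal(f1$p_values, f3$p_values, tolerance = 1e-8)
  expect_equal(f1$adj_r_squared, f3$adj_r_squared, tolerance = 1e-10)
})

test_that("aliased predictors are dropped with a warning", {
  set.seed(55)
  X <- data.frame(a = rnorm(12))
  X$b <- 2 * X$a
  expect_warning(fit <- ols_sequential(rnorm(12), X), "aliased")
  expect_identical(fit$order, "a")
})

test_that("univariate variation partitioning mirrors the multivariate identities", {
  set.seed(56)
  y <- rnorm(30)
  E <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("e1", "e2")))
  S2 <- E; colnames(S2) <- c("s1", "s2")
  vp <- cwm_variation_partition(y, E, S2)
  expect_equal(unname(vp$fractions["a"]), 0, tolerance = 1e-10)
  expect_equal(unname(vp$fractions["c"]), 0, tolerance = 1e-10)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-10)
  expect_error(cwm_variation_partition(y, E, S2[, 1, drop = FALSE]), "equal")
})

test_that("single-column forward selection reduces to univariate F ranking", {
  set.seed(57)
  y <- rnorm(40)
  C <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("v", 1:5)))
  C[, 2] <- y + rnorm(40, sd = 0.4)
  sel <- forward_select(matrix(y), C, n_perm = 99, seed = 1)
  f_uni <- vapply(colnames(C), function(v)
    summary(lm(y ~ C[, v]))$fstatistic[["value"]], numeric(1))
  expect_identical(sel[1], names(which.max(f_uni)))
})

test_that("the fitted moisture effect on CWM moisture preference recovers the simulated sign", {
  set.seed(58)
  ok <- vapply(1:20, function(i) {
    ds <- tiny_dataset(seed = i, scenario = "strong_filtering")
    cwm <- community_weighted_mean(ds$abundance, scale_trait_table(ds$traits))
    fit <- ols_sequential(cwm[, "moisture_preference"],
                          data.frame(soil_moisture = ds$env$soil_moisture,
                                     topography = ds$env$topography))
    fit$signs[["soil_moisture"]] > 0
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("per-trait CWM regression tables carry equal-count predictor sets", {
  ds <- tiny_dataset(seed = 9, scenario = "strong_filtering")
  cwm <- community_weighted_mean(ds$abundance, scale_trait_table(ds$traits))
  E <- scale(as.matrix(ds$env), scale = FALSE)
  S <- pcnm(cbind(ds$points$x, ds$points$y))$vectors
  tab <- suppressWarnings(
    cwm_regression_table(cwm[, 1:2], E, S, n_perm = 49, seed = 1))
  for (tr in names(tab)) {
    expect_equal(length(tab[[tr]]$selected_env),
                 length(tab[[tr]]$selected_spatial))
    expect_equal(sum(tab[[tr]]$fractions$fractions), 1, tolerance = 1e-10)
    expect_true(all(c("variable", "set", "sign", "p_value", "flagged") %in%
                    colnames(tab[[tr]]$summary)))
  }
})
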