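test_that("Hellinger rows are square-rooted relative abundances", {
  expect_equal(hellinger(matrix(1, 1, 4)), matrix(0.5, 1, 4))
  expect_equal(hellinger(matrix(c(9, 16, 0), 1)), matrix(c(0.6, 0.8, 0), 1))
  A <- random_abundance(6, 5, seed = 1)
  H <- hellinger(A)
  expect_equal(rowSums(H^2), setNames(rep(1, 6), rownames(A)))
  expect_equal(unname(H), unname(as.matrix(
    vegan::decostand(A, method = "hellinger"))), ignore_attr = TRUE)
  A[2, ] <- 0
  expect_warning(H0 <- hellinger(A), "zero rows")
  expect_true(all(H0[2, ] == 0))
  expect_error(hellinger(matrix(-1, 2, 2)), "nonnegative")
})

test_that("rda recovers perfect fits and exact orthogonality", {
  set.seed(41)
  x <- rnorm(10)
  fit <- rda_fit(matrix(x), matrix(x + 5))
  expect_equal(fit$r_squared, 1)
  y <- matrix(rnorm(20), 10, 2)
  yc <- sweep(y, 2, colMeans(y))
  xo <- qr.resid(qr(cbind(1, yc)), rnorm(10))   # orthogonal to centred Y
  expect_equal(rda_fit(y, matrix(xo))$r_squared, 0, tolerance = 1e-12)
})

test_that("rda matches the normal-equations oracle and vegan", {
  set.seed(42)
  Y <- matrix(rnorm(18), 6, 3)
  X <- matrix(rnorm(12), 6, 2)
  fit <- rda_fit(Y, X)
  oracle <- oracle_rda(Y, X)
  expect_equal(fit$r_squared, oracle$r2, tolerance = 1e-10)
  expect_equal(fit$eigenvalues, oracle$eigenvalues, tolerance = 1e-10)
  expect_equal(sum(fit$eigenvalues) / fit$total_variance, fit$r_squared,
               tolerance = 1e-10)
  v <- vegan::rda(Y ~ X)
  expect_equal(fit$r_squared,
               v$CCA$tot.chi / v$tot.chi, tolerance = 1e-10)
  expect_equal(fit$eigenvalues, unname(v$CCA$eig), tolerance = 1e-10)
})

test_that("rda is invariant to predictor rescaling and drops aliased columns", {
  set.seed(43)
  Y <- matrix(rnorm(30), 10, 3)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  f1 <- rda_fit(Y, X)
  f2 <- rda_fit(Y, sweep(X, 2, c(100, 0.01), "*"))
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
  Xa <- cbind(X, c = X[, 1] * 2)
  expect_warning(fa <- rda_fit(Y, Xa), "aliased")
  expect_equal(fa$r_squared, f1$r_squared, tolerance = 1e-10)
  expect_equal(fa$m, 2)
})

test_that("partial rda residualises both sides and reports semipartial R2", {
  set.seed(44)
  Y <- matrix(rnorm(40), 10, 4)
  X <- matrix(rnorm(20), 10, 2)
  W <- matrix(rnorm(10), 10, 1)
  expect_equal(partial_rda(Y, X, NULL)$r_squared, rda_fit(Y, X)$r_squared)
  # oracle: two explicit residualisation steps
  Yc <- sweep(Y, 2, colMeans(Y)); Xc <- sweep(X, 2, colMeans(X))
  Wc <- sweep(W, 2, colMeans(W))
  Pw <- Wc %*% solve(t(Wc) %*% Wc) %*% t(Wc)
  Yr <- Yc - Pw %*% Yc; Xr <- Xc - Pw %*% Xc
  Yhat <- Xr %*% solve(t(Xr) %*% Xr) %*% t(Xr) %*% Yr
  expect_equal(partial_rda(Y, X, W)$r_squared, sum(Yhat^2) / sum(Yc^2),
               tolerance = 1e-10)
  # X inside span(W): nothing left to explain
  expect_warning(f0 <- partial_rda(Y, W * 3, W), "aliased")
  expect_equal(f0$r_squared, 0, tolerance = 1e-12)
})

test_that("pseudo-F permutation p-values respect their bounds", {
  set.seed(45)
  X <- matrix(rnorm(20), 20, 1)
  Y <- cbind(2 * X + rnorm(20, sd = 1e-4), -X + rnorm(20, sd = 1e-4))
  t1 <- pseudo_f_test(Y, X, n_perm = 99, seed = 1)
  expect_equal(t1$p_value, 1 / 100)     # floor attained for a near-exact fit
  Yn <- matrix(rnorm(40), 20, 2)
  t2 <- pseudo_f_test(Yn, X, n_perm = 49, seed = 2)
  expect_gte(t2$p_value, 1 / 50)
  expect_lte(t2$p_value, 1)
  t3 <- pseudo_f_test(Yn, X, n_perm = 49, seed = 2)
  expect_identical(t2$p_value, t3$p_value)
})

test_that("partial pseudo-F uses reduced-model residual permutations", {
  set.seed(46)
  W <- matrix(rnorm(25), 25, 1)
  X <- matrix(rnorm(25), 25, 1)
  Y <- cbind(W + rnorm(25, sd = 0.1), rnorm(25))
  t <- pseudo_f_test(Y, X, W, n_perm = 99, seed = 3)
  expect_identical(t$scheme, "residuals_reduced")
  expect_true(t$p_value >= 1 / 100 && t$p_value <= 1)
})

test_that("forward selection picks obvious signals first and stops on noise", {
  set.seed(47)
  expect_identical(
    forward_select(matrix(rnorm(20)), matrix(numeric(0), 20, 0)),
    character(0))
  Y <- matrix(rnorm(60), 30, 2)
  C <- cbind(sig = Y[, 1], matrix(rnorm(90), 30, 3,
             dimnames = list(NULL, paste0("n", 1:3))))
  sel <- forward_select(Y, C, n_perm = 99, seed = 1)
  expect_identical(sel[1], "sig")
  # all-noise candidates: selection is usually empty at alpha = 0.05
  empty <- vapply(1:30, function(i) {
    Yn <- matrix(rnorm(100), 50, 2)
    Cn <- matrix(rnorm(50 * 8), 50, 8,
                 dimnames = list(NULL, paste0("c", 1:8)))
    length(forward_select(Yn, Cn, n_perm = 99, seed = i)) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.6)
})

test_that("variation partitioning fractions obey their identities", {
  set.seed(48)
  Y <- matrix(rnorm(60), 20, 3)
  E <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("e1", "e2")))
  S <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("s1", "s2")))
  vp <- variation_partition(Y, E, S)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-10)
  expect_gte(vp$r2[["ES"]], max(vp$r2[["E"]], vp$r2[["S"]]))
  # identical matrices under different labels: everything is shared
  S2 <- E; colnames(S2) <- c("s1", "s2")
  vp2 <- variation_partition(Y, E, S2)
  expect_equal(unname(vp2$fractions["a"]), 0, tolerance = 1e-10)
  expect_equal(unname(vp2$fractions["c"]), 0, tolerance = 1e-10)
  expect_equal(unname(vp2$fractions["b"]), vp2$r2[["E"]], tolerance = 1e-10)
  expect_error(variation_partition(Y, E, E), "overlapping")
})

test_that("orthogonal additive predictors give a near-zero shared fraction", {
  set.seed(49)
  n <- 500
  M <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  E <- M[, 1:2, drop = FALSE]; colnames(E) <- c("e1", "e2")
  S <- M[, 3:4, drop = FALSE]; colnames(S) <- c("s1", "s2")
  Y <- E %*% matrix(c(1, 0.5, -0.3, 0.8), 2) +
       S %*% matrix(c(-0.6, 0.2, 0.9, -0.4), 2) + matrix(rnorm(2 * n, sd = 0.5), n)
  vp <- variation_partition(Y, E, S)
  expect_lt(abs(vp$fractions[["b"]]), 0.02)
})

test_that("the shared fraction dominates for filtered communities on a structured environment", {
  # environment variation almost fully spatially structured at resolvable
  # scale; moderate filtering keeps the composition response near-linear
  ok <- vapply(1:5, function(s) {
    pts <- generate_nested_design(seed = s)
    fp <- field_params(range_m = 15, nugget_frac = 0.01, topo_trend_sd = 0,
                       moisture_topo_slope = -30)
    env <- simulate_environment(pts, fp, seed = s + 100)
    tr <- simulate_trait_table(20, seed = s + 200)
    ab <- simulate_community(pts, env, tr,
      community_params(filtering_strength = 4, niche_width = 12,
                       baseline_abundance = 30), seed = s + 300)
    ds <- drop_empty_samples(marsh_dataset(pts, env, tr, ab))
    Yh <- hellinger(ds$abundance)
    P <- pcnm(cbind(ds$points$x, ds$points$y))$vectors
    E <- scale(as.matrix(ds$env), scale = FALSE)
    sel_s <- suppressWarnings(forward_select(Yh, P, n_perm = 99, seed = 3))
    sel_e <- suppressWarnings(forward_select(Yh, E, n_perm = 99, seed = 3))
    f <- variation_partition(Yh, E[, sel_e, drop = FALSE],
                             P[, sel_s, drop = FALSE])$fractions
    f[["b"]] > f[["a"]] && f[["b"]] > f[["c"]]
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})
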