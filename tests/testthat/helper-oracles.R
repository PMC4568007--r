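# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/.

# Prim's algorithm: total MST length and maximum edge.
prim_mst <- function(D) {
  dimnames(D) <- NULL
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  total <- 0; max_edge <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    total <- total + best[j]
    max_edge <- max(max_edge, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  list(total = total, max_edge = max_edge)
}

# Principal-coordinate analysis by explicit elementwise double-centring.
oracle_pcoa <- function(Dstar) {
  A <- -0.5 * Dstar^2
  n <- nrow(A)
  B <- matrix(0, n, n)
  rm <- rowMeans(A); cm <- colMeans(A); gm <- mean(A)
  for (i in seq_len(n)) for (j in seq_len(n))
    B[i, j] <- A[i, j] - rm[i] - cm[j] + gm
  eigen(B, symmetric = TRUE)
}

# Multivariate least squares via explicit normal equations, plus the
# eigenvalues of the fitted covariance.
oracle_rda <- function(Y, X) {
  Yc <- sweep(Y, 2, colMeans(Y))
  Xc <- sweep(X, 2, colMeans(X))
  B <- solve(t(Xc) %*% Xc) %*% t(Xc) %*% Yc
  Yhat <- Xc %*% B
  r2 <- sum(Yhat^2) / sum(Yc^2)
  ev <- eigen(t(Yhat) %*% Yhat / (nrow(Y) - 1), symmetric = TRUE)$values
  list(r2 = r2, eigenvalues = ev[ev > 1e-12], coef = B)
}

# Rao's Q by explicit double summation.
oracle_rao <- function(p, D) {
  q <- 0
  for (i in seq_along(p)) for (j in seq_along(p))
    q <- q + D[i, j] * p[i] * p[j]
  q
}

# Ordinary-kriging weights from one dense solve using all data points.
oracle_kriging <- function(coords, z, model, target) {
  n <- nrow(coords)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    G[i, j] <- model_gamma(model, sqrt(sum((coords[i, ] - coords[j, ])^2)))
  g0 <- vapply(seq_len(n), function(i)
    model_gamma(model, sqrt(sum((coords[i, ] - target)^2))), numeric(1))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  sol <- solve(A, c(g0, 1))
  list(weights = sol[seq_len(n)], mu = sol[n + 1],
       prediction = sum(sol[seq_len(n)] * z),
       variance = sum(sol[seq_len(n)] * g0) + sol[n + 1])
}

# Small synthetic dataset for fast tests (80 samples with the default
# 5-node layout; empty samples dropped).
tiny_dataset <- function(seed = 1, scenario = "default", ...) {
  drop_empty_samples(simulate_dataset(
    scenario, seed = seed, n_nodes = 5, n_infill = 0, ...))
}

# Random abundance matrix with guaranteed nonempty rows.
random_abundance <- function(n, s, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rpois(n * s, 3), n, s,
              dimnames = list(paste0("s", seq_len(n)), paste0("sp", seq_len(s))))
  empty <- rowSums(A) == 0
  A[empty, 1] <- 1
  A
}

# Random trait dissimilarity matrix in [0, 1].
random_dissim <- function(s, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- matrix(runif(s * s), s, s)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(paste0("sp", seq_len(s)), paste0("sp", seq_len(s)))
  D
}
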