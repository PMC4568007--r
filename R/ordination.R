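#' Hellinger transformation of community data
#'
#' `y'_ik = sqrt(y_ik / y_k+)` row-wise: square roots of relative
#' abundances, making zero-rich community data suitable for linear
#' (Euclidean) ordination without overweighting rare species. Every nonzero
#' row of the result has unit sum of squares. Zero rows stay zero, with a
#' warning.
#'
#' @param abundance nonnegative samples-by-species matrix.
#' @return transformed matrix of the same shape.
#' @export
hellinger <- function(abundance) {
  A <- .check_numeric_matrix(abundance, "abundance")
  if (any(A < 0)) stop("abundances must be nonnegative")
  w <- rowSums(A)
  if (any(w == 0)) {
    warning("zero rows remain zero under the Hellinger transformation: ",
            paste(rownames(A)[w == 0], collapse = ", "))
    w[w == 0] <- 1
  }
  sqrt(A / w)
}

# QR projection helper: returns fitted values of Y on the (centred) columns
# of X, plus rank and the labels of aliased (dropped) columns.
.proj <- function(X, tol = 1e-8) {
  qrX <- qr(X, tol = tol)
  labs <- colnames(X)
  if (is.null(labs)) labs <- paste0("column ", seq_len(ncol(X)))
  aliased <- if (qrX$rank < ncol(X))
    labs[qrX$pivot[(qrX$rank + 1):ncol(X)]] else character(0)
  list(qr = qrX, rank = qrX$rank, aliased = aliased)
}

.fitted_on <- function(proj, Y) {
  if (proj$rank == 0) return(matrix(0, nrow(Y), ncol(Y)))
  qr.fitted(proj$qr, Y)
}

# Residualise X on the projection pw, zeroing columns whose residual norm is
# negligible relative to the original column (they lie inside span(W); a QR
# on the raw residuals would otherwise promote numerical noise to full
# projectors, since projection is scale-invariant).
.resid_on <- function(pw, X) {
  R <- X - .fitted_on(pw, X)
  tiny <- sqrt(colSums(R^2)) < 1e-8 * pmax(sqrt(colSums(X^2)), 1e-300)
  if (any(tiny)) R[, tiny] <- 0
  R
}

#' Redundancy analysis (RDA)
#'
#' Constrained linear ordination: `Y` is column-centred, regressed on the
#' centred predictors `X` by multivariate least squares, and the fitted
#' values are eigen-decomposed. `R^2` is the sum of canonical eigenvalues
#' divided by the total variance of `Y` (equivalently
#' `trace(Yhat'Yhat)/trace(Y'Y)`); the adjusted `R^2` uses the Ezekiel
#' correction `1 - (1 - R^2)(n - 1)/(n - m - 1)`. Rank-deficient predictor
#' sets have their aliased columns dropped with a warning.
#'
#' @param Y response matrix (samples x variables), centred internally.
#' @param X predictor matrix, centred internally.
#' @return list of class `"rda_result"`: `r_squared`, `adj_r_squared`,
#'   `eigenvalues` (canonical), `total_variance`, `site_scores`,
#'   `coefficients`, `n`, `m` (predictor rank), `q` (conditioning rank, 0),
#'   `aliased`.
#' @export
rda_fit <- function(Y, X) {
  Yc <- .center(.check_numeric_matrix(Y, "Y"))
  Xc <- .center(.check_numeric_matrix(X, "X"))
  n <- nrow(Yc)
  if (nrow(Xc) != n) stop("Y and X must have the same number of rows")
  px <- .proj(Xc)
  if (length(px$aliased))
    warning("aliased predictors dropped: ", paste(px$aliased, collapse = ", "))
  if (n <= px$rank + 1) stop("too few samples: n must exceed rank(X) + 1")
  .rda_from_proj(Yc, Xc, px, total = sum(Yc^2), q = 0L)
}

.rda_from_proj <- function(Yc, Xc, px, total, q) {
  n <- nrow(Yc)
  Yhat <- .fitted_on(px, Yc)
  r2 <- sum(Yhat^2) / total
  eig <- eigen(crossprod(Yhat) / (n - 1), symmetric = TRUE)
  keep <- eig$values > 1e-12 * max(eig$values, 1e-300)
  values <- eig$values[keep]
  scores <- Yhat %*% eig$vectors[, keep, drop = FALSE]
  if (ncol(scores) > 0)
    colnames(scores) <- paste0("RDA", seq_len(ncol(scores)))
  coefs <- tryCatch(qr.coef(px$qr, Yc), error = function(e) NULL)
  m <- px$rank
  structure(list(
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - m - q - 1),
    eigenvalues = values, total_variance = total / (n - 1),
    site_scores = scores, coefficients = coefs,
    n = n, m = m, q = q, aliased = px$aliased), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "RDA: n = %d, m = %d%s\n  R2 = %.4f  adj R2 = %.4f  canonical eigenvalues: %s\n",
    x$n, x$m, if (x$q > 0) sprintf(" (conditioned on %d)", x$q) else "",
    x$r_squared, x$adj_r_squared,
    paste(signif(head(x$eigenvalues, 5), 4), collapse = ", ")))
  invisible(x)
}

#' Partial redundancy analysis
#'
#' Both `Y` and `X` are replaced by their residuals on the conditioning
#' matrix `W` before the RDA; the reported `R^2` is the *semipartial*
#' fraction, i.e. explained variance as a fraction of the original total
#' variance of `Y`, so that fractions from different conditionings are
#' directly comparable in variation partitioning.
#'
#' @inheritParams rda_fit
#' @param W conditioning (covariable) matrix; `NULL` or zero columns means
#'   an ordinary [rda_fit()].
#' @export
partial_rda <- function(Y, X, W = NULL) {
  if (is.null(W) || NCOL(W) == 0) return(rda_fit(Y, X))
  Yc <- .center(.check_numeric_matrix(Y, "Y"))
  Xc <- .center(.check_numeric_matrix(X, "X"))
  Wc <- .center(.check_numeric_matrix(W, "W"))
  pw <- .proj(Wc)
  Yr <- Yc - .fitted_on(pw, Yc)
  Xr <- .resid_on(pw, Xc)
  px <- .proj(Xr)
  if (length(px$aliased))
    warning("aliased predictors dropped: ", paste(px$aliased, collapse = ", "))
  n <- nrow(Yc)
  if (n <= px$rank + pw$rank + 1) stop("too few samples for the partial model")
  .rda_from_proj(Yr, Xr, px, total = sum(Yc^2), q = pw$rank)
}

#' Permutation pseudo-F test for (partial) RDA
#'
#' Tests the variance explained by `X` (after the conditioning set `W`, if
#' any) with the pseudo-F statistic
#' `F = (R2_X / m) / ((1 - R2_W - R2_X) / (n - m - q - 1))`, where `R2_X`
#' is the semipartial fraction of `X` and `R2_W` that of `W` alone. Simple
#' models permute the rows of `Y` (`scheme = "raw"`); partial models
#' permute the residuals of the reduced model, i.e. of `Y` on `W`
#' (`scheme = "residuals_reduced"`, the Freedman--Lane scheme). The p-value
#' is `(#\{F_perm >= F_obs\} + 1) / (n_perm + 1)`.
#'
#' @inheritParams partial_rda
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @param scheme `"auto"` (raw without `W`, reduced-model residuals with),
#'   `"raw"`, or `"residuals_reduced"`.
#' @return list of class `"permutation_test"`: `statistic` (pseudo-F),
#'   `p_value`, `r_squared` (semipartial for `X`), `n_perm`, `scheme`.
#' @export
pseudo_f_test <- function(Y, X, W = NULL, n_perm = 999, seed = NULL,
                          scheme = c("auto", "raw", "residuals_reduced")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("'n_perm' must be at least 1")
  Yc <- .center(.check_numeric_matrix(Y, "Y"))
  Xc <- .center(.check_numeric_matrix(X, "X"))
  has_w <- !is.null(W) && NCOL(W) > 0
  if (scheme == "auto") scheme <- if (has_w) "residuals_reduced" else "raw"
  Wc <- if (has_w) .center(.check_numeric_matrix(W, "W")) else NULL
  n <- nrow(Yc)
  pw <- if (has_w) .proj(Wc) else NULL
  q <- if (has_w) pw$rank else 0L

  fitW <- if (has_w) .fitted_on(pw, Yc) else matrix(0, n, ncol(Yc))
  Yr <- Yc - fitW
  Xr <- if (has_w) .resid_on(pw, Xc) else Xc
  px <- .proj(Xr)
  m <- px$rank
  df_res <- n - m - q - 1
  if (df_res < 1) stop("saturated model: no residual degrees of freedom")

  f_stat <- function(Ywhole) {
    tot <- sum(Ywhole^2)
    r2w <- if (has_w) sum(.fitted_on(pw, Ywhole)^2) / tot else 0
    Yres <- if (has_w) Ywhole - .fitted_on(pw, Ywhole) else Ywhole
    r2x <- sum(.fitted_on(px, Yres)^2) / tot
    denom <- 1 - r2w - r2x
    list(f = (r2x / m) / (denom / df_res), r2 = r2x)
  }
  obs <- f_stat(Yc)
  .set_seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    Yp <- if (scheme == "raw") Yc[idx, , drop = FALSE]
          else fitW + Yr[idx, , drop = FALSE]
    if (f_stat(Yp)$f >= obs$f) exceed <- exceed + 1L
  }
  structure(list(statistic = obs$f, p_value = (exceed + 1) / (n_perm + 1),
                 r_squared = obs$r2, n_perm = n_perm, scheme = scheme,
                 m = m, q = q, seed = seed), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "Permutation pseudo-F test (%s, %d permutations)\n  F = %.4f  semipartial R2 = %.4f  p = %.4f\n",
    x$scheme, x$n_perm, x$statistic, x$r_squared, x$p_value))
  invisible(x)
}

#' Permutation-based forward selection of predictors
#'
#' Greedy forward selection: at each step the candidate with the highest
#' added-variance pseudo-F conditioned on the already-selected set is
#' tested by permutation of the reduced-model residuals, and added if its
#' p-value is at most `alpha`. Selection stops at the first failure or at
#' `max_k` predictors.
#'
#' @param Y response matrix.
#' @param candidates labelled candidate predictor matrix.
#' @param alpha inclusion threshold on the permutation p-value.
#' @param n_perm permutations per inclusion test.
#' @param max_k maximum number of predictors to select.
#' @param seed optional integer seed.
#' @return character vector of selected labels in inclusion order, with a
#'   `"selection"` attribute (data.frame: label, F, p, cumulative R2).
#' @export
forward_select <- function(Y, candidates, alpha = 0.05, n_perm = 999,
                           max_k = Inf, seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  C <- .check_numeric_matrix(candidates, "candidates")
  if (ncol(C) == 0) return(character(0))
  if (is.null(colnames(C))) stop("'candidates' must have column labels")
  Yc <- .center(.check_numeric_matrix(Y, "Y"))
  labels <- colnames(C)
  if (length(labels) == 0) return(character(0))
  seeds <- .derive_seeds(seed, min(length(labels), nrow(Yc)))
  selected <- character(0)
  log <- list()
  while (length(selected) < min(max_k, length(labels))) {
    remaining <- setdiff(labels, selected)
    if (!length(remaining)) break
    W <- if (length(selected)) C[, selected, drop = FALSE] else NULL
    fs <- vapply(remaining, function(lab) {
      tryCatch(
        .quick_f(Yc, C[, lab, drop = FALSE], W),
        error = function(e) -Inf)
    }, numeric(1))
    best <- remaining[which.max(fs)]
    if (!is.finite(max(fs))) break
    test <- pseudo_f_test(Yc, C[, best, drop = FALSE], W, n_perm = n_perm,
                          seed = seeds[[length(selected) + 1]],
                          scheme = if (is.null(W)) "raw" else "residuals_reduced")
    if (test$p_value > alpha) break
    selected <- c(selected, best)
    cum <- rda_fit(Yc, C[, selected, drop = FALSE])$r_squared
    log[[length(log) + 1]] <- data.frame(
      label = best, pseudo_f = test$statistic, p_value = test$p_value,
      added_r2 = test$r_squared, cum_r2 = cum)
  }
  structure(selected,
            selection = if (length(log)) do.call(rbind, log) else NULL)
}

# Pseudo-F of one candidate given conditioning set, no permutations.
.quick_f <- function(Yc, x, W) {
  n <- nrow(Yc)
  has_w <- !is.null(W)
  tot <- sum(Yc^2)
  if (has_w) {
    pw <- .proj(.center(W))
    r2w <- sum(.fitted_on(pw, Yc)^2) / tot
    Yr <- Yc - .fitted_on(pw, Yc)
    xr <- .resid_on(pw, .center(x))
    q <- pw$rank
  } else {
    r2w <- 0; Yr <- Yc; xr <- .center(x); q <- 0L
  }
  px <- .proj(xr)
  if (px$rank == 0) return(-Inf)
  r2x <- sum(.fitted_on(px, Yr)^2) / tot
  (r2x / px$rank) / ((1 - r2w - r2x) / (n - px$rank - q - 1))
}

#' Variation partitioning between environment and space
#'
#' Decomposes the variance of `Y` explained by two predictor sets into the
#' pure environmental fraction `a = R2(E+S) - R2(S)`, the shared fraction
#' `b = R2(E) + R2(S) - R2(E+S)`, the pure spatial fraction
#' `c = R2(E+S) - R2(E)` and the residual `d = 1 - R2(E+S)`. The default
#' accounting is unadjusted `R^2` from the sum of canonical eigenvalues;
#' `adjusted = TRUE` uses Ezekiel-adjusted `R^2` instead. A negative shared
#' fraction (suppression) is reported as-is, never truncated.
#'
#' @param Y response matrix.
#' @param E,S labelled predictor matrices (no shared column labels).
#' @param adjusted use adjusted `R^2`.
#' @return list of class `"varpart_result"`: `fractions` (a, b, c, d),
#'   `r2` (E, S, ES), `adjusted`, `n`.
#' @export
variation_partition <- function(Y, E, S, adjusted = FALSE) {
  E <- .check_numeric_matrix(E, "E"); S <- .check_numeric_matrix(S, "S")
  shared <- intersect(colnames(E), colnames(S))
  if (length(shared))
    stop("overlapping column labels between E and S: ",
         paste(shared, collapse = ", "))
  r2 <- function(X) {
    fit <- rda_fit(Y, X)
    if (adjusted) fit$adj_r_squared else fit$r_squared
  }
  r2e <- r2(E); r2s <- r2(S); r2es <- r2(cbind(E, S))
  fr <- c(a = r2es - r2s, b = r2e + r2s - r2es, c = r2es - r2e, d = 1 - r2es)
  structure(list(fractions = fr, r2 = c(E = r2e, S = r2s, ES = r2es),
                 adjusted = adjusted, n = nrow(as.matrix(Y))),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  f <- x$fractions
  expl <- sum(f[c("a", "b", "c")])
  cat(sprintf("Variation partitioning (%s R2, n = %d)\n",
              if (x$adjusted) "adjusted" else "unadjusted", x$n))
  cat(sprintf("  pure environment  a = E|S  = %6.3f  (%5.1f%% of total, %5.1f%% of explained)\n",
              f["a"], 100 * f["a"], 100 * f["a"] / expl))
  cat(sprintf("  shared            b = S&E  = %6.3f  (%5.1f%% of total, %5.1f%% of explained)\n",
              f["b"], 100 * f["b"], 100 * f["b"] / expl))
  cat(sprintf("  pure space        c = S|E  = %6.3f  (%5.1f%% of total, %5.1f%% of explained)\n",
              f["c"], 100 * f["c"], 100 * f["c"] / expl))
  cat(sprintf("  residual          d        = %6.3f\n", f["d"]))
  invisible(x)
}
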