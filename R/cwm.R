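#' Transform environment variables and drop collinear ones
#'
#' Applies ln transforms (with an optional `+ epsilon` guard for zeros) and
#' square-root transforms (for percentages and zero-rich counts) to the
#' named variables, then iteratively removes one variable of every pair
#' with `|Pearson r|` above `corr_threshold`; of the offending pair, the
#' variable with the larger mean absolute correlation to all other
#' variables is dropped. Every decision is recorded.
#'
#' @param env sample-by-variable environment data.frame.
#' @param ln_vars variables to ln-transform.
#' @param sqrt_vars variables to square-root-transform.
#' @param corr_threshold collinearity cutoff on `|r|`, in `(0, 1]`.
#' @param ln_eps added inside the ln; with the default 0, nonpositive
#'   values raise an error pointing at this option.
#' @return transformed data.frame; attribute `"log"` is a character vector
#'   of transform/drop decisions, attribute `"dropped"` the dropped names.
#' @export
preprocess_environment <- function(env, ln_vars = character(0),
                                   sqrt_vars = character(0),
                                   corr_threshold = 0.6, ln_eps = 0) {
  env <- as.data.frame(env)
  if (corr_threshold <= 0 || corr_threshold > 1)
    stop("'corr_threshold' must be in (0, 1]")
  missing <- setdiff(c(ln_vars, sqrt_vars), colnames(env))
  if (length(missing)) stop("unknown variables: ", paste(missing, collapse = ", "))
  log <- character(0)
  for (v in ln_vars) {
    if (any(env[[v]] + ln_eps <= 0))
      stop(sprintf(
        "variable '%s' has nonpositive values; use the 'ln_eps' option", v))
    env[[v]] <- log(env[[v]] + ln_eps)
    log <- c(log, sprintf("ln-transformed '%s' (eps = %g)", v, ln_eps))
  }
  for (v in sqrt_vars) {
    if (any(env[[v]] < 0)) stop(sprintf("variable '%s' has negative values", v))
    env[[v]] <- sqrt(env[[v]])
    log <- c(log, sprintf("sqrt-transformed '%s'", v))
  }
  dropped <- character(0)
  repeat {
    if (ncol(env) < 2) break
    r <- abs(cor(env))
    diag(r) <- 0
    if (max(r) <= corr_threshold) break
    pair <- which(r == max(r), arr.ind = TRUE)[1, ]
    meanr <- rowMeans(r)
    drop <- colnames(env)[pair[which.max(meanr[pair])]]
    log <- c(log, sprintf(
      "dropped '%s' (|r| = %.3f with '%s' exceeds %.2f)", drop, max(r),
      setdiff(colnames(env)[pair], drop), corr_threshold))
    dropped <- c(dropped, drop)
    env <- env[, setdiff(colnames(env), drop), drop = FALSE]
  }
  attr(env, "log") <- log
  attr(env, "dropped") <- dropped
  env
}

#' Multiple regression with sequential sum-of-squares decomposition
#'
#' Ordinary least squares of one response on centred predictors, reporting
#' Type-I (sequential) sums of squares in the given predictor order --
#' the decomposition used to rank predictors by the variance they explain
#' -- together with coefficients (whose signs give the direction of each
#' relationship), per-variable F-test p-values, the residual sum of squares
#' and the adjusted `R^2`. Aliased columns are dropped with a warning.
#'
#' @param y numeric response vector.
#' @param X predictor matrix/data.frame with column labels.
#' @param order predictor order for the sequential decomposition; default
#'   is the column order of `X`.
#' @return list of class `"regression_result"`: `coefficients` (without
#'   intercept), `signs`, `r_squared`, `adj_r_squared`, `sequential_ss`,
#'   `residual_ss`, `total_ss`, `p_values`, `order`.
#' @export
ols_sequential <- function(y, X, order = NULL) {
  X <- as.data.frame(X)
  if (is.null(colnames(X))) stop("'X' must have column labels")
  if (is.null(order)) order <- colnames(X)
  if (!all(order %in% colnames(X))) stop("'order' names unknown predictors")
  X <- X[, order, drop = FALSE]
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("'y' and 'X' lengths differ")
  if (length(y) <= ncol(X) + 1) stop("too few observations")
  Xc <- as.data.frame(.center(as.matrix(X)))
  fit <- lm(y ~ ., data = cbind(data.frame(y = y), Xc))
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    warning("aliased predictors dropped: ", paste(bad, collapse = ", "))
    keep <- setdiff(order, bad)
    return(ols_sequential(y, X[, keep, drop = FALSE], keep))
  }
  an <- anova(fit)
  k <- ncol(Xc)
  seq_ss <- setNames(an$`Sum Sq`[seq_len(k)], rownames(an)[seq_len(k)])
  res_ss <- an$`Sum Sq`[k + 1]
  smry <- summary(fit)
  coefs <- coef(fit)[-1]
  structure(list(
    coefficients = coefs, signs = sign(coefs),
    r_squared = smry$r.squared, adj_r_squared = smry$adj.r.squared,
    sequential_ss = seq_ss, residual_ss = res_ss,
    total_ss = sum(seq_ss) + res_ss,
    p_values = setNames(an$`Pr(>F)`[seq_len(k)], names(seq_ss)),
    order = order, fit = fit), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Sequential OLS: adj R2 = %.3f, residual SS = %.4g\n",
              x$adj_r_squared, x$residual_ss))
  tab <- data.frame(coef = x$coefficients, seq_ss = x$sequential_ss,
                    p = x$p_values)
  print(signif(as.matrix(tab), 4))
  invisible(x)
}

#' Univariate variation partitioning for one CWM trait
#'
#' Same arithmetic as [variation_partition()] but with `R^2` from
#' univariate OLS of one community-weighted-mean trait on the selected
#' environmental and spatial predictor sets. The two sets must contain
#' equal numbers of predictors so their fractions are comparable.
#'
#' @param y numeric response (one CWM trait across samples).
#' @param E_selected,S_selected equal-sized labelled predictor matrices.
#' @param adjusted use adjusted `R^2`.
#' @return a `"varpart_result"` (fractions a, b, c, d).
#' @export
cwm_variation_partition <- function(y, E_selected, S_selected, adjusted = FALSE) {
  E <- .check_numeric_matrix(E_selected, "E_selected")
  S <- .check_numeric_matrix(S_selected, "S_selected")
  if (ncol(E) != ncol(S))
    stop("E and S must contain equal numbers of predictors")
  variation_partition(matrix(as.numeric(y), ncol = 1), E, S, adjusted = adjusted)
}

#' Per-trait CWM regressions with equal-count spatial predictors
#'
#' For each community-weighted-mean trait: forward-selects environmental
#' predictors, takes the same number of spatial predictors (in their own
#' forward-selection inclusion order), fits the combined sequential OLS,
#' and partitions the trait's variance into pure environmental, shared and
#' pure spatial fractions. Forward-selected variables whose sequential
#' p-value exceeds 0.05 in the final model are retained but flagged.
#'
#' @param cwm samples-by-traits CWM matrix (see [community_weighted_mean()]).
#' @param env preprocessed environment table.
#' @param spatial spatial predictor matrix (PCNM axes or trend surface).
#' @param alpha,n_perm forward-selection settings.
#' @param seed optional integer seed.
#' @param min_k if forward selection selects nothing for a set, fall back
#'   to the `min_k` best candidates by marginal fit (default 1).
#' @return list with one entry per trait: `selected_env`, `selected_spatial`,
#'   `regression` (a `"regression_result"`), `fractions` (varpart), and a
#'   `summary` data.frame analogous to a multiple-regression summary table
#'   (variable, set, sign, sequential SS, p, flagged).
#' @export
cwm_regression_table <- function(cwm, env, spatial, alpha = 0.05,
                                 n_perm = 999, seed = NULL, min_k = 1) {
  cwm <- .check_numeric_matrix(cwm, "cwm")
  E <- .check_numeric_matrix(env, "env")
  S <- .check_numeric_matrix(spatial, "spatial")
  seeds <- .derive_seeds(seed, 2L * ncol(cwm))
  out <- list()
  for (j in seq_len(ncol(cwm))) {
    trait <- colnames(cwm)[j]
    y <- cwm[, j]
    sel_e <- forward_select(y, E, alpha = alpha, n_perm = n_perm,
                            seed = seeds[[2 * j - 1]])
    if (length(sel_e) < min_k) sel_e <- .top_marginal(y, E, min_k)
    sel_s <- forward_select(y, S, alpha = alpha, n_perm = n_perm,
                            max_k = length(sel_e), seed = seeds[[2 * j]])
    if (length(sel_s) < length(sel_e))
      sel_s <- unique(c(sel_s, .top_marginal(y, S, length(sel_e) - length(sel_s),
                                             exclude = sel_s)))
    ord <- c(sel_e, sel_s)
    reg <- ols_sequential(y, cbind(E[, sel_e, drop = FALSE],
                                   S[, sel_s, drop = FALSE]), ord)
    fr <- cwm_variation_partition(y, E[, sel_e, drop = FALSE],
                                  S[, sel_s, drop = FALSE])
    out[[trait]] <- list(
      selected_env = sel_e, selected_spatial = sel_s, regression = reg,
      fractions = fr,
      summary = data.frame(
        variable = ord,
        set = rep(c("environment", "spatial"), c(length(sel_e), length(sel_s))),
        sign = reg$signs[ord], sequential_ss = reg$sequential_ss[ord],
        p_value = reg$p_values[ord],
        flagged = reg$p_values[ord] > 0.05, row.names = NULL))
  }
  out
}

# Best k candidates by marginal univariate R2 (used as an equal-count
# fallback when permutation selection stops early).
.top_marginal <- function(y, X, k, exclude = character(0)) {
  if (k < 1) return(character(0))
  cand <- setdiff(colnames(X), exclude)
  r2 <- vapply(cand, function(lab)
    summary(lm(y ~ X[, lab]))$r.squared, numeric(1))
  cand[order(r2, decreasing = TRUE)][seq_len(min(k, length(cand)))]
}
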