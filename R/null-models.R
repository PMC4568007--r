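#' Randomise species identities within communities
#'
#' The identity-randomisation null model for trait dispersion: for each
#' sample with richness `S_k`, `S_k` species are drawn without replacement
#' from the full pool and the sample's observed abundance values are
#' reassigned to them. Per-sample richness and the multiset of abundance
#' values are preserved exactly; only which trait values the abundances
#' attach to is randomised. `mode = "pool_shuffle"` instead applies one
#' global permutation of species identities to the whole matrix.
#'
#' @param abundance samples-by-species count matrix.
#' @param species_pool pool of species labels (must contain all species in
#'   `abundance`); defaults to the observed species set.
#' @param seed optional integer seed.
#' @param mode `"per_community"` (default) or `"pool_shuffle"`.
#' @return count matrix with columns = `species_pool`.
#' @export
randomize_identities <- function(abundance, species_pool = colnames(abundance),
                                 seed = NULL,
                                 mode = c("per_community", "pool_shuffle")) {
  mode <- match.arg(mode)
  A <- .check_numeric_matrix(abundance, "abundance")
  if (is.null(colnames(A))) stop("'abundance' needs species column names")
  if (!all(colnames(A) %in% species_pool))
    stop("species_pool must contain every species in 'abundance'")
  npool <- length(species_pool)
  .set_seed(seed)

  if (mode == "pool_shuffle") {
    out <- matrix(0, nrow(A), npool,
                  dimnames = list(rownames(A), species_pool))
    out[, sample(species_pool, ncol(A))] <- A
    return(out)
  }
  out <- matrix(0, nrow(A), npool, dimnames = list(rownames(A), species_pool))
  for (k in seq_len(nrow(A))) {
    present <- which(A[k, ] > 0)
    S <- length(present)
    if (S > npool) stop("sample richness exceeds the species pool size")
    if (S == 0) next
    out[k, sample.int(npool, S)] <- A[k, present]
  }
  out
}

#' One-sided permutation test of trait dispersion against an identity null
#'
#' Compares an observed diversity statistic -- the mean alpha diversity
#' (`"alpha_mean"`) or the percentage beta turnover (`"beta_pct"`), both on
#' the equivalent-number scale by default -- with its distribution over
#' `n_reps` identity randomisations ([randomize_identities()]). Both
#' one-sided p-values are reported: `p_low` (observed smaller than the null,
#' the signature of trait underdispersion for alpha) and `p_high`. Ties
#' count toward rejection in both tails, so
#' `p_low + p_high >= 1 + 1/(n_reps + 1)`.
#'
#' @param abundance samples-by-species counts (no empty rows).
#' @param D species dissimilarity matrix over the full pool.
#' @param statistic `"alpha_mean"` or `"beta_pct"`.
#' @param n_reps number of null randomisations (paper-style default 499).
#' @param seed optional integer seed.
#' @param mode randomisation mode, see [randomize_identities()].
#' @param scale `"equivalent"` (Jost scale, default) or `"raw"` Q.
#' @return list of class `"null_model_result"`: `observed`, `null` (vector),
#'   `p_low`, `p_high`, `n_reps`, `statistic`.
#' @export
null_test <- function(abundance, D, statistic = c("alpha_mean", "beta_pct"),
                      n_reps = 499, seed = NULL,
                      mode = c("per_community", "pool_shuffle"),
                      scale = c("equivalent", "raw")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  if (n_reps < 1) stop("'n_reps' must be at least 1")
  A <- .check_numeric_matrix(abundance, "abundance")
  if (any(rowSums(A) == 0)) stop("empty sample rows are not allowed")
  D <- as.matrix(D)
  pool <- colnames(A)
  if (!is.null(rownames(D))) D <- D[pool, pool]
  if (all(D == 0))
    warning("degenerate dissimilarity matrix (all zeros): statistic is ",
            "constant and p-values equal 1 by the tie rule")
  .set_seed(seed)

  stat_fun <- function(M) {
    w <- rowSums(M)
    pc <- .partition_core(M / w, D, w)
    if (statistic == "alpha_mean") {
      if (scale == "equivalent") pc$mean_alpha_eq else mean(pc$alpha_raw)
    } else {
      if (scale == "equivalent") pc$pct_beta
      else 100 * (pc$gamma_raw - mean(pc$alpha_raw)) / pc$gamma_raw
    }
  }
  observed <- stat_fun(A)
  nulls <- vapply(seq_len(n_reps), function(r) {
    stat_fun(randomize_identities(A, pool, seed = NULL, mode = mode))
  }, numeric(1))

  structure(list(
    observed = observed, null = nulls,
    p_low = (sum(nulls <= observed) + 1) / (n_reps + 1),
    p_high = (sum(nulls >= observed) + 1) / (n_reps + 1),
    n_reps = n_reps, statistic = statistic, scale = scale, seed = seed),
    class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  q <- quantile(x$null, c(0.025, 0.975))
  cat(sprintf(
    "Null-model test of %s (%s scale, %d replicates)\n  observed = %.4f  null mean = %.4f  [2.5%%, 97.5%%] = [%.4f, %.4f]\n  p_low = %.4f  p_high = %.4f\n",
    x$statistic, x$scale, x$n_reps, x$observed, mean(x$null), q[1], q[2],
    x$p_low, x$p_high))
  invisible(x)
}

#' Null-model dispersion tests across trait sets
#'
#' Runs [null_test()] for mean alpha and percentage beta on the multi-trait
#' dissimilarity and on each single trait: a tabular analogue of the
#' bar-and-flagpole dispersion figure (observed value against the null
#' envelope per trait).
#'
#' @param abundance samples-by-species counts.
#' @param scaled_traits scaled species-by-trait table.
#' @param n_reps,seed,mode passed to [null_test()].
#' @return data.frame with one row per facet x statistic: observed, null
#'   mean, null 2.5/97.5 percentiles, `p_low`, `p_high`.
#' @export
null_test_table <- function(abundance, scaled_traits, n_reps = 499,
                            seed = NULL, mode = "per_community") {
  facets <- c("multi_trait", colnames(scaled_traits))
  seeds <- .derive_seeds(seed, 2L * length(facets))
  rows <- list(); i <- 0
  for (f in facets) {
    D <- if (f == "multi_trait") trait_dissimilarity(scaled_traits)
         else trait_dissimilarity(scaled_traits, f)
    for (st in c("alpha_mean", "beta_pct")) {
      i <- i + 1
      r <- null_test(abundance, D, st, n_reps = n_reps, seed = seeds[[i]],
                     mode = mode)
      q <- quantile(r$null, c(0.025, 0.975))
      rows[[i]] <- data.frame(
        facet = f, statistic = st, observed = r$observed,
        null_mean = mean(r$null), null_q025 = q[[1]], null_q975 = q[[2]],
        p_low = r$p_low, p_high = r$p_high)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
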