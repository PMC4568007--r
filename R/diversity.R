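#' Scale trait values linearly to [0, 1]
#'
#' Linear map `(x - raw_min) / (raw_max - raw_min)`, the standard rescaling
#' that gives every trait equal weight in multi-trait dissimilarities.
#'
#' @param raw_values numeric vector.
#' @param raw_min,raw_max scaling range; defaults to the observed range of
#'   the analysed species pool.
#' @return numeric vector in `[0, 1]`.
#' @export
scale_trait <- function(raw_values, raw_min = min(raw_values),
                        raw_max = max(raw_values)) {
  if (raw_max <= raw_min)
    stop("constant trait: raw_max must exceed raw_min")
  if (any(raw_values < raw_min | raw_values > raw_max))
    stop("trait values outside [raw_min, raw_max]")
  (raw_values - raw_min) / (raw_max - raw_min)
}

#' Scale a whole species-by-trait table to [0, 1]
#'
#' Continuous and count-valued traits (body length, antenna ratio, habitat
#' width) are scaled by the observed min/max of the species pool; ordinal
#' traits already coded on `[0, 1]` (life form, moisture preference) are
#' kept exactly as coded.
#'
#' @param traits raw species-by-trait data.frame or matrix.
#' @param coded traits whose codings are already on `[0, 1]` and must be
#'   kept verbatim.
#' @return data.frame of scaled values with a `"trait_ranges"` attribute
#'   recording each trait's scaling range (`NA` for identity-coded traits).
#' @export
scale_trait_table <- function(traits,
                              coded = c("life_form", "moisture_preference")) {
  traits <- as.data.frame(traits)
  out <- traits
  ranges <- matrix(NA_real_, 2, ncol(traits),
                   dimnames = list(c("min", "max"), colnames(traits)))
  for (j in seq_along(traits)) {
    x <- traits[[j]]
    nm <- colnames(traits)[j]
    if (!is.numeric(x)) stop("trait '", nm, "' is not numeric")
    if (nm %in% coded) {
      if (min(x) < 0 || max(x) > 1)
        stop("coded trait '", nm, "' has values outside [0, 1]")
      next
    }
    ranges[, j] <- range(x)
    out[[j]] <- scale_trait(x)
  }
  attr(out, "trait_ranges") <- ranges
  out
}

#' Pairwise trait dissimilarity between species
#'
#' Single trait: `d_ij = |x_i - x_j|`. Several traits: the Gower mean of the
#' per-trait absolute differences, `d_ij = (1/T) * sum_t |x_it - x_jt|`,
#' which keeps `d` in `[0, 1]` so that the equivalent-number (Jost)
#' transform of Rao's Q stays finite. `combine = "sum"` accepts the raw-sum
#' convention but rescales by `1/T` anyway, with a warning.
#'
#' @param scaled_traits species-by-trait table with all values in `[0, 1]`
#'   (see [scale_trait_table()]).
#' @param trait_subset traits to use; default all.
#' @param combine `"mean"` (default, Gower) or `"sum"` (rescaled, warns).
#' @return symmetric species-by-species matrix with zero diagonal,
#'   `d_ij` in `[0, 1]`.
#' @export
trait_dissimilarity <- function(scaled_traits, trait_subset = NULL,
                                combine = c("mean", "sum")) {
  combine <- match.arg(combine)
  scaled_traits <- as.data.frame(scaled_traits)
  if (is.null(trait_subset)) trait_subset <- colnames(scaled_traits)
  if (length(trait_subset) == 0) stop("empty trait subset")
  missing <- setdiff(trait_subset, colnames(scaled_traits))
  if (length(missing)) stop("unknown traits: ", paste(missing, collapse = ", "))
  X <- as.matrix(scaled_traits[, trait_subset, drop = FALSE])
  if (any(X < 0 | X > 1)) stop("traits must be scaled to [0, 1] first")
  if (combine == "sum")
    warning("combine = 'sum' is rescaled by 1/T to keep d in [0, 1]")
  D <- matrix(0, nrow(X), nrow(X), dimnames = list(rownames(X), rownames(X)))
  for (t in seq_len(ncol(X)))
    D <- D + abs(outer(X[, t], X[, t], "-"))
  D / ncol(X)
}

.check_rel_abund <- function(p, D = NULL) {
  if (any(p < 0)) stop("relative abundances must be nonnegative")
  if (abs(sum(p) - 1) > 1e-8) stop("relative abundances must sum to 1")
  if (!is.null(D)) {
    D <- as.matrix(D)
    if (nrow(D) != length(p) || ncol(D) != length(p))
      stop("dimension mismatch between p and D")
    if (max(abs(D - t(D))) > 1e-10 || any(diag(D) != 0))
      stop("D must be symmetric with zero diagonal")
  }
  invisible(TRUE)
}

#' Rao's quadratic entropy
#'
#' `Q = sum_ij d_ij p_i p_j`: the expected trait dissimilarity between two
#' individuals drawn at random from the community. With all off-diagonal
#' `d_ij = 1` it reduces to the Simpson index.
#'
#' @param p relative abundances (nonnegative, summing to 1).
#' @param D species dissimilarity matrix (symmetric, zero diagonal).
#' @return scalar Q.
#' @export
rao_q <- function(p, D) {
  .check_rel_abund(p, D)
  drop(crossprod(p, as.matrix(D) %*% p))
}

#' Simpson diversity index
#'
#' `1 - sum(p_i^2)`; equals [rao_q()] with unit dissimilarity between all
#' distinct species.
#'
#' @inheritParams rao_q
#' @export
simpson_diversity <- function(p) {
  .check_rel_abund(p)
  1 - sum(p^2)
}

#' Equivalent numbers (Jost correction) for Simpson-family indices
#'
#' Transforms a concave index value `Q` in `[0, 1)` to the effective-number
#' scale `1 / (1 - Q)`, on which additive alpha/beta/gamma partitioning is
#' well behaved.
#'
#' @param Q index value(s) in `[0, 1)`.
#' @export
equivalent_number <- function(Q) {
  if (any(Q < 0) || any(Q >= 1))
    stop("Q must lie in [0, 1) for the equivalent-number transform")
  1 / (1 - Q)
}

# Fast unvalidated partition: P = relative-abundance rows, w = row totals.
.partition_core <- function(P, D, w, alpha_weighting = "unweighted",
                            jost = "per_sample") {
  alpha_raw <- rowSums((P %*% D) * P)
  pbar <- colSums(P * w) / sum(w)
  gamma_raw <- drop(crossprod(pbar, D %*% pbar))
  gamma_eq <- 1 / (1 - gamma_raw)
  wts <- if (alpha_weighting == "abundance") w / sum(w) else rep(1 / nrow(P), nrow(P))
  mean_alpha_eq <- if (jost == "per_sample") sum(wts / (1 - alpha_raw))
                   else 1 / (1 - sum(wts * alpha_raw))
  list(alpha_raw = alpha_raw, gamma_raw = gamma_raw, gamma_eq = gamma_eq,
       mean_alpha_eq = mean_alpha_eq, beta_add = gamma_eq - mean_alpha_eq,
       pct_alpha = 100 * mean_alpha_eq / gamma_eq,
       pct_beta = 100 * (gamma_eq - mean_alpha_eq) / gamma_eq)
}

#' Additive alpha/beta/gamma diversity partitioning on the equivalent-number scale
#'
#' Computes Rao's Q for every sample (alpha) and for the pooled relative
#' abundances of the whole set (gamma), transforms to equivalent numbers
#' (`1/(1-Q)`), and partitions additively: `beta = gamma - mean(alpha)`.
#' By default the Jost transform is applied per sample before averaging and
#' samples are weighted equally; both choices can be switched.
#'
#' When `D` is omitted, unit dissimilarities are used and the partition is a
#' Simpson *species*-diversity partition.
#'
#' @param abundance samples-by-species count (or abundance) matrix; every
#'   row must contain at least one individual.
#' @param D species dissimilarity matrix; `NULL` for species diversity.
#' @param alpha_weighting `"unweighted"` (default) or `"abundance"`.
#' @param jost `"per_sample"` (transform each alpha, then average; default)
#'   or `"of_mean"` (transform the averaged raw alpha).
#' @return list of class `"diversity_partition"`: `gamma_eq`,
#'   `mean_alpha_eq`, `beta_add`, `pct_alpha`, `pct_beta`, per-sample
#'   `alpha_raw` and pooled `gamma_raw`.
#' @export
partition_diversity <- function(abundance, D = NULL,
                                alpha_weighting = c("unweighted", "abundance"),
                                jost = c("per_sample", "of_mean")) {
  alpha_weighting <- match.arg(alpha_weighting)
  jost <- match.arg(jost)
  A <- .check_numeric_matrix(abundance, "abundance")
  if (any(A < 0)) stop("abundances must be nonnegative")
  if (nrow(A) < 2) stop("at least 2 samples are required")
  w <- rowSums(A)
  if (any(w == 0))
    stop("empty sample rows: ",
         paste(rownames(A)[w == 0], collapse = ", "))
  if (is.null(D)) {
    D <- 1 - diag(ncol(A))
    dimnames(D) <- list(colnames(A), colnames(A))
  }
  D <- as.matrix(D)
  if (!is.null(colnames(A)) && !is.null(rownames(D))) {
    if (!all(colnames(A) %in% rownames(D)))
      stop("species missing from D: ",
           paste(setdiff(colnames(A), rownames(D)), collapse = ", "))
    D <- D[colnames(A), colnames(A)]
  } else if (ncol(A) != nrow(D)) stop("species mismatch between abundance and D")
  P <- A / w
  out <- .partition_core(P, D, w, alpha_weighting, jost)
  out$n_samples <- nrow(A)
  class(out) <- "diversity_partition"
  out
}

#' @export
print.diversity_partition <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Diversity partition (%d samples)\n  gamma_eq = %.*f  mean alpha_eq = %.*f  beta_add = %.*f\n  %%alpha = %.1f  %%beta = %.1f\n",
    x$n_samples, digits, x$gamma_eq, digits, x$mean_alpha_eq, digits,
    x$beta_add, x$pct_alpha, x$pct_beta))
  invisible(x)
}

#' Community-weighted mean trait values
#'
#' `CWM_kt = sum_i p_ik x_it`: per-sample trait means weighted by species
#' relative abundances. Samples with zero total abundance get `NA` rows with
#' a warning (never a silent 0).
#'
#' @param abundance samples-by-species counts.
#' @param scaled_traits species-by-trait table covering all species present.
#' @return samples-by-traits numeric matrix.
#' @export
community_weighted_mean <- function(abundance, scaled_traits) {
  A <- .check_numeric_matrix(abundance, "abundance")
  X <- as.matrix(as.data.frame(scaled_traits))
  if (!all(colnames(A) %in% rownames(X)))
    stop("traits missing for species: ",
         paste(setdiff(colnames(A), rownames(X)), collapse = ", "))
  X <- X[colnames(A), , drop = FALSE]
  w <- rowSums(A)
  cwm <- (A %*% X) / w
  if (any(w == 0)) {
    warning("samples with zero abundance set to NA: ",
            paste(rownames(A)[w == 0], collapse = ", "))
    cwm[w == 0, ] <- NA_real_
  }
  cwm
}

#' Diversity-partition summary table across trait sets
#'
#' One row per diversity facet: Simpson species diversity, multi-trait Rao
#' over all traits, and single-trait Rao for each trait; columns give the
#' gamma equivalent number and the percentage alpha and beta contributions.
#'
#' @param abundance samples-by-species counts.
#' @param scaled_traits scaled species-by-trait table.
#' @param ... passed to [partition_diversity()].
#' @return data.frame with columns `facet`, `gamma_eq`, `pct_alpha`, `pct_beta`.
#' @export
diversity_partition_table <- function(abundance, scaled_traits, ...) {
  facets <- c("species", "multi_trait", colnames(scaled_traits))
  rows <- lapply(facets, function(f) {
    D <- if (f == "species") NULL
         else if (f == "multi_trait") trait_dissimilarity(scaled_traits)
         else trait_dissimilarity(scaled_traits, f)
    p <- partition_diversity(abundance, D, ...)
    data.frame(facet = f, gamma_eq = p$gamma_eq,
               pct_alpha = p$pct_alpha, pct_beta = p$pct_beta)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
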