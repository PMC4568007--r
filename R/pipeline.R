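#' Read aligned survey tables from delimited text files
#'
#' Reads the abundance, environment, coordinate and trait tables (CSV,
#' header row, sample or species ids in the first column) and aligns them
#' by id, erroring with the offending ids on any mismatch or duplication.
#'
#' @param abundance,env,coords,traits file paths.
#' @return a [marsh_dataset()].
#' @export
read_tables <- function(abundance, env, coords, traits) {
  rd <- function(path, numeric_cols = NULL) {
    x <- utils::read.csv(path, check.names = FALSE)
    ids <- as.character(x[[1]])
    if (anyDuplicated(ids))
      stop(sprintf("duplicate ids in '%s': %s", path,
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    out <- x[, -1, drop = FALSE]
    check <- if (is.null(numeric_cols)) colnames(out)
             else intersect(numeric_cols, colnames(out))
    bad <- check[!vapply(out[check], is.numeric, logical(1))]
    if (length(bad))
      stop(sprintf("non-numeric cells in '%s' (%s)", path,
                   paste(bad, collapse = ", ")))
    rownames(out) <- ids
    out
  }
  ab <- rd(abundance); en <- rd(env)
  co <- rd(coords, numeric_cols = c("x", "y"))
  tr <- rd(traits)
  if (!all(c("x", "y") %in% colnames(co)))
    stop("coordinate table must have 'x' and 'y' columns")
  ids <- rownames(co)
  for (nm in c("abundance", "env")) {
    tab <- if (nm == "abundance") ab else en
    extra <- setdiff(rownames(tab), ids)
    miss <- setdiff(ids, rownames(tab))
    if (length(extra) || length(miss))
      stop(sprintf("sample ids of '%s' do not match coords (missing: %s; extra: %s)",
                   nm, paste(miss, collapse = ", "), paste(extra, collapse = ", ")))
  }
  pts <- data.frame(point_id = ids, x = co$x, y = co$y,
                    node_id = if ("node_id" %in% colnames(co)) co$node_id else NA,
                    series_id = if ("series_id" %in% colnames(co)) co$series_id else NA,
                    step_distance = NA_real_, row.names = ids)
  class(pts) <- c("sample_points", "data.frame")
  marsh_dataset(pts, en[ids, , drop = FALSE], tr,
                as.matrix(ab[ids, , drop = FALSE]))
}

#' Write a dataset's tables as CSV files
#'
#' Writes `coords.csv` (point_id, x, y, node_id, series_id),
#' `abundance.csv`, `env.csv` and `traits.csv` (comma-delimited, UTF-8,
#' `.` decimal) into `dir`.
#'
#' @param dataset a [marsh_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tab, name, id_col) {
    df <- cbind(setNames(data.frame(rownames(tab)), id_col),
                as.data.frame(tab))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  pts <- dataset$points
  utils::write.csv(
    data.frame(point_id = pts$point_id, x = pts$x, y = pts$y,
               node_id = pts$node_id, series_id = pts$series_id),
    file.path(dir, "coords.csv"), row.names = FALSE)
  wr(dataset$abundance, "abundance.csv", "sample_id")
  wr(dataset$env, "env.csv", "sample_id")
  wr(dataset$traits, "traits.csv", "species")
  invisible(dir)
}

#' Run the full trait-based spatial analysis
#'
#' End-to-end orchestrator over one dataset: (1) environment preprocessing
#' (transformations and the collinearity filter); (2) additive diversity
#' partitioning of species, multi-trait and single-trait diversity; (3)
#' identity-null dispersion tests; (4) spatial predictors (PCNM or trend
#' surface); (5) permutation forward selection of environmental and spatial
#' variables, truncated to equal counts; (6) variation partitioning of the
#' Hellinger-transformed species matrix and of the CWM trait matrix; (7)
#' per-trait CWM regressions with sequential-SS decomposition and
#' univariate variation partitioning; (8) semivariogram fitting with
#' cross-validation model selection for each environment variable and for
#' the first-axis RDA site scores. All stage seeds derive from one master
#' seed, so a fixed seed makes the whole report reproducible.
#'
#' @param dataset a [marsh_dataset()].
#' @param spatial_method `"pcnm"` or `"trend"`.
#' @param trend_degree trend-surface degree when `spatial_method = "trend"`.
#' @param null_reps null-model replicates.
#' @param n_perm permutations for pseudo-F tests and forward selection.
#' @param alpha forward-selection inclusion threshold.
#' @param ln_vars,sqrt_vars,corr_threshold environment preprocessing
#'   settings (defaults follow the package's salt-marsh variables).
#' @param variogram_k kriging neighbours for cross-validation.
#' @param seed master integer seed.
#' @return list of class `"analysis_report"` with elements
#'   `diversity_partition`, `null_tests`, `selected` (env/spatial labels),
#'   `varpart_species`, `varpart_cwm`, `model_tests`, `cwm_regressions`,
#'   `variograms`, `rda_scores`, `seed`, `settings`.
#' @export
run_full_analysis <- function(dataset,
                              spatial_method = c("pcnm", "trend"),
                              trend_degree = 3,
                              null_reps = 499, n_perm = 999, alpha = 0.05,
                              ln_vars = c("vegetation_height",
                                          "litter_thickness", "litter_mass"),
                              sqrt_vars = c("soil_moisture", "n_stems"),
                              corr_threshold = 0.6,
                              variogram_k = 5,
                              seed = NULL) {
  spatial_method <- match.arg(spatial_method)
  if (!inherits(dataset, "marsh_dataset")) stop("'dataset' must be a marsh_dataset")
  seeds <- .derive_seeds(seed, 6L)
  ab <- dataset$abundance
  nonempty <- rowSums(ab) > 0
  if (!all(nonempty)) {
    message("dropping ", sum(!nonempty), " empty sample(s)")
    dataset$points <- dataset$points[nonempty, , drop = FALSE]
    dataset$env <- dataset$env[nonempty, , drop = FALSE]
    ab <- ab[nonempty, , drop = FALSE]
  }
  scaled <- scale_trait_table(dataset$traits)

  env <- preprocess_environment(
    dataset$env,
    ln_vars = intersect(ln_vars, colnames(dataset$env)),
    sqrt_vars = intersect(sqrt_vars, colnames(dataset$env)),
    corr_threshold = corr_threshold, ln_eps = 1)
  E <- .center(as.matrix(env))

  partition <- diversity_partition_table(ab, scaled)
  nulls <- null_test_table(ab, scaled, n_reps = null_reps, seed = seeds[[1]])

  coords <- cbind(dataset$points$x, dataset$points$y)
  S <- if (spatial_method == "pcnm") pcnm(coords)$vectors
       else trend_surface(coords, trend_degree)

  Yh <- hellinger(ab)
  sel_e <- forward_select(Yh, E, alpha = alpha, n_perm = n_perm,
                          seed = seeds[[2]])
  sel_s <- forward_select(Yh, S, alpha = alpha, n_perm = n_perm,
                          seed = seeds[[3]])
  k <- max(1L, min(length(sel_e), length(sel_s)))
  if (length(sel_e) < 1) sel_e <- .top_marginal_multi(Yh, E, 1)
  if (length(sel_s) < 1) sel_s <- .top_marginal_multi(Yh, S, 1)
  sel_e <- head(sel_e, k); sel_s <- head(sel_s, k)
  Ek <- E[, sel_e, drop = FALSE]; Sk <- S[, sel_s, drop = FALSE]

  vp_sp <- variation_partition(Yh, Ek, Sk)
  tests <- list(
    environment = pseudo_f_test(Yh, Ek, Sk, n_perm = n_perm, seed = seeds[[4]]),
    space = pseudo_f_test(Yh, Sk, Ek, n_perm = n_perm, seed = seeds[[4]]),
    full = pseudo_f_test(Yh, cbind(Ek, Sk), n_perm = n_perm, seed = seeds[[4]]))

  cwm <- community_weighted_mean(ab, scaled)
  vp_cwm <- variation_partition(.center(cwm), Ek, Sk)
  cwm_reg <- cwm_regression_table(cwm, E, S, alpha = alpha, n_perm = n_perm,
                                  seed = seeds[[5]])

  full_rda <- rda_fit(Yh, cbind(Ek, Sk))
  cwm_rda <- rda_fit(.center(cwm), cbind(Ek, Sk))
  scores <- cbind(species_axis1 = full_rda$site_scores[, 1],
                  cwm_axis1 = cwm_rda$site_scores[, 1])

  vario_vars <- cbind(as.matrix(dataset$env), scores)
  variograms <- lapply(setNames(colnames(vario_vars), colnames(vario_vars)),
                       function(v) {
    emp <- empirical_semivariogram(coords, vario_vars[, v])
    fits <- lapply(c("spherical", "exponential", "gaussian"), function(ty)
      tryCatch(fit_variogram(emp, ty), error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) return(NULL)
    cv <- loo_cross_validation(coords, vario_vars[, v], fits, k = variogram_k)
    list(empirical = emp, model = cv$model, rmse = cv$rmse)
  })

  structure(list(
    diversity_partition = partition, null_tests = nulls,
    selected = list(environment = sel_e, spatial = sel_s),
    varpart_species = vp_sp, varpart_cwm = vp_cwm, model_tests = tests,
    cwm_regressions = cwm_reg, variograms = variograms, rda_scores = scores,
    seed = seed,
    settings = list(spatial_method = spatial_method, null_reps = null_reps,
                    n_perm = n_perm, alpha = alpha,
                    env_log = attr(env, "log"))),
    class = "analysis_report")
}

# Multivariate analogue of .top_marginal: rank candidates by marginal RDA R2.
.top_marginal_multi <- function(Y, X, k) {
  r2 <- vapply(colnames(X), function(lab)
    rda_fit(Y, X[, lab, drop = FALSE])$r_squared, numeric(1))
  colnames(X)[order(r2, decreasing = TRUE)][seq_len(min(k, ncol(X)))]
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Trait-based spatial community analysis\n\n")
  cat("Diversity partition (equivalent numbers):\n")
  print(transform(x$diversity_partition,
                  gamma_eq = round(gamma_eq, 2),
                  pct_alpha = round(pct_alpha, 1),
                  pct_beta = round(pct_beta, 1)))
  cat(sprintf("\nSelected variables: environment = {%s}; spatial = {%s}\n",
              paste(x$selected$environment, collapse = ", "),
              paste(x$selected$spatial, collapse = ", ")))
  cat("\nVariation partitioning, species composition:\n")
  print(x$varpart_species)
  cat("\nVariation partitioning, CWM traits:\n")
  print(x$varpart_cwm)
  ranges <- vapply(x$variograms, function(v)
    if (is.null(v)) NA_real_ else v$model$range, numeric(1))
  cat("\nFitted autocorrelation ranges (m):\n")
  print(round(ranges, 2))
  invisible(x)
}

#' Write an analysis report as CSV tables
#'
#' Emits `diversity_partition.csv`, `null_tests.csv`, `varpart.csv`,
#' `cwm_regressions.csv`, `variogram_fits.csv` and a `run_log.txt` (seed
#' and settings) into `dir`.
#'
#' @param report an `"analysis_report"`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$diversity_partition,
                   file.path(dir, "diversity_partition.csv"), row.names = FALSE)
  utils::write.csv(report$null_tests, file.path(dir, "null_tests.csv"),
                   row.names = FALSE)
  vp <- rbind(
    data.frame(response = "species", t(report$varpart_species$fractions)),
    data.frame(response = "cwm", t(report$varpart_cwm$fractions)))
  utils::write.csv(vp, file.path(dir, "varpart.csv"), row.names = FALSE)
  reg <- do.call(rbind, lapply(names(report$cwm_regressions), function(tr) {
    s <- report$cwm_regressions[[tr]]$summary
    cbind(trait = tr, s,
          adj_r_squared = report$cwm_regressions[[tr]]$regression$adj_r_squared)
  }))
  utils::write.csv(reg, file.path(dir, "cwm_regressions.csv"), row.names = FALSE)
  vg <- do.call(rbind, lapply(names(report$variograms), function(v) {
    m <- report$variograms[[v]]
    if (is.null(m)) return(NULL)
    data.frame(variable = v, model = m$model$type, nugget = m$model$nugget,
               psill = m$model$psill, range = m$model$range,
               cv_rmse = min(m$rmse))
  }))
  utils::write.csv(vg, file.path(dir, "variogram_fits.csv"), row.names = FALSE)
  writeLines(c(sprintf("seed: %s", deparse(report$seed)),
               sprintf("spatial_method: %s", report$settings$spatial_method),
               sprintf("null_reps: %d", report$settings$null_reps),
               sprintf("n_perm: %d", report$settings$n_perm),
               sprintf("alpha: %g", report$settings$alpha),
               report$settings$env_log),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
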