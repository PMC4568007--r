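#' Parameters of the synthetic environment fields
#'
#' All base fields share one exponential spatial-covariance structure
#' (practical-range convention: correlation drops to ~5% at `range_m`).
#' `sill` is a master variance multiplier: every field's spatial standard
#' deviation is scaled by `sqrt(sill)`, so `sill = 0` yields constant fields.
#' Soil moisture and litter thickness are coupled to topography through
#' linear slopes plus an independent field, mimicking the low but nonzero
#' correlations among measured salt-marsh variables; the default
#' moisture-on-topography slope is negative (depressions stay wet).
#'
#' Topography additionally carries a broad plot-scale component
#' (`topo_trend_sd`, `trend_range_m`): natural elevation varies at nested
#' scales -- a gentle cross-plot gradient (e.g. between drainage creeks)
#' on top of metre-scale microtopography -- and the coupled moisture and
#' litter fields inherit both scales through their slopes.
#'
#' @param range_m autocorrelation (practical) range in metres of the
#'   local (fine-scale) fields.
#' @param sill master variance multiplier (>= 0).
#' @param nugget_frac fraction of each field's variance that is spatially
#'   unstructured, in `[0, 1]`.
#' @param topo_mean,topo_sd relative elevation mean and local-component SD (m).
#' @param topo_trend_sd SD (m) of the broad plot-scale elevation component;
#'   0 removes it.
#' @param trend_range_m practical range (m) of the broad component.
#' @param moisture_mean,moisture_sd soil moisture mean and independent SD (%).
#' @param moisture_topo_slope moisture change per metre of elevation (%/m).
#' @param litter_mean,litter_sd litter-layer thickness mean and SD (mm).
#' @param litter_topo_slope litter-thickness change per metre elevation (mm/m).
#' @param veg_mean,veg_log_sd vegetation height: median (mm) and log-scale SD.
#' @param stems_log_mean,stems_log_sd log-scale mean and SD of stem counts.
#' @return A validated list of class `"field_params"`.
#' @export
field_params <- function(range_m = 5, sill = 1, nugget_frac = 0.1,
                         topo_mean = 1.65, topo_sd = 0.11,
                         topo_trend_sd = 0.11, trend_range_m = 20,
                         moisture_mean = 55, moisture_sd = 8,
                         moisture_topo_slope = -30,
                         litter_mean = 15, litter_sd = 6,
                         litter_topo_slope = -15,
                         veg_mean = 300, veg_log_sd = 0.35,
                         stems_log_mean = log(3), stems_log_sd = 0.8) {
  if (range_m <= 0 || trend_range_m <= 0) stop("ranges must be positive")
  if (topo_trend_sd < 0) stop("'topo_trend_sd' must be nonnegative")
  if (sill < 0) stop("'sill' must be nonnegative")
  if (nugget_frac < 0 || nugget_frac > 1) stop("'nugget_frac' must be in [0, 1]")
  structure(as.list(environment()), class = "field_params")
}

# Draw n_draws independent unit-variance Gaussian random fields with
# exponential covariance C(h) = (1 - nugget) exp(-3 h / range) + nugget * I,
# by dense Cholesky factorisation (intended for n <= ~500 points).
.grf_unit <- function(coords, range_m, nugget_frac, n_draws) {
  h <- as.matrix(dist(coords))
  C <- (1 - nugget_frac) * exp(-3 * h / range_m)
  diag(C) <- 1
  L <- tryCatch(chol(C), error = function(e)
    stop("singular spatial covariance (duplicate points with zero nugget?): ",
         conditionMessage(e), call. = FALSE))
  z <- matrix(rnorm(nrow(h) * n_draws), nrow(h), n_draws)
  crossprod(L, z)
}

#' Simulate spatially autocorrelated environment fields at sample points
#'
#' Generates the six environment variables of a late-successional salt-marsh
#' plot -- relative topography (m), soil moisture (%), litter-layer thickness
#' (mm), litter mass (g), vegetation height (mm) and stem counts -- as
#' Gaussian random fields with exponential covariance. Moisture and litter
#' thickness are linear in topography plus an independent field; moisture is
#' clipped to `[0, 100]`, thicknesses and masses to nonnegative values, and
#' stem counts are nonnegative integers.
#'
#' @param points a `sample_points` table (or any data.frame with `x`, `y`).
#' @param params a [field_params()] object.
#' @param seed optional integer seed.
#' @return A data.frame (one row per sample point, rownames = point ids) with
#'   columns `topography`, `soil_moisture`, `litter_thickness`,
#'   `litter_mass`, `vegetation_height`, `n_stems`.
#' @export
simulate_environment <- function(points, params = field_params(), seed = NULL) {
  if (!inherits(params, "field_params")) stop("'params' must be a field_params object")
  coords <- cbind(points$x, points$y)
  if (nrow(coords) < 2) stop("at least 2 points are required")
  .set_seed(seed)
  p <- params
  s <- sqrt(p$sill)
  g <- .grf_unit(coords, p$range_m, p$nugget_frac, 6L)
  broad <- if (p$topo_trend_sd > 0)   # tiny nugget keeps chol stable at 0-distance pairs
    .grf_unit(coords, p$trend_range_m, 1e-6, 1L)[, 1] else 0

  topo <- p$topo_mean + p$topo_trend_sd * s * broad + p$topo_sd * s * g[, 1]
  moisture <- p$moisture_mean + p$moisture_topo_slope * (topo - p$topo_mean) +
    p$moisture_sd * s * g[, 2]
  moisture <- pmin(pmax(moisture, 0), 100)
  litter <- p$litter_mean + p$litter_topo_slope * (topo - p$topo_mean) +
    p$litter_sd * s * g[, 3]
  litter <- pmax(litter, 0)
  litter_mass <- 0.08 * litter * exp(0.3 * s * g[, 4])
  veg <- p$veg_mean * exp(p$veg_log_sd * s * g[, 5])
  stems <- round(exp(p$stems_log_mean + p$stems_log_sd * s * g[, 6]))

  out <- data.frame(topography = topo, soil_moisture = moisture,
                    litter_thickness = litter, litter_mass = litter_mass,
                    vegetation_height = veg, n_stems = as.integer(stems))
  rownames(out) <- if (!is.null(points$point_id)) points$point_id else rownames(points)
  out
}

#' Simulate a species-by-trait table
#'
#' Draws a species pool with the five collembolan traits used throughout the
#' package: body length (mm, 0.5--5.4), antenna-to-body-length ratio
#' (0.1--0.7), life form (epigeic 1 / hemiedaphic 0.5 / euedaphic 0),
#' moisture preference (five ordinal classes from xerophile 0 to hygrophile
#' 1) and habitat width (number of habitat types, 1--9).
#'
#' @param n_species pool size.
#' @param seed optional integer seed.
#' @return data.frame of raw trait values, rownames `sp01`, `sp02`, ...
#' @export
simulate_trait_table <- function(n_species = 20, seed = NULL) {
  if (n_species < 2) stop("'n_species' must be at least 2")
  .set_seed(seed)
  out <- data.frame(
    body_length = round(runif(n_species, 0.5, 5.4), 1),
    antenna_ratio = round(runif(n_species, 0.1, 0.7), 2),
    life_form = sample(c(0, 0.5, 1), n_species, replace = TRUE),
    moisture_preference = sample(c(0, 0.25, 0.5, 0.75, 1), n_species, replace = TRUE),
    habitat_width = sample(1:9, n_species, replace = TRUE))
  rownames(out) <- sprintf("sp%02d", seq_len(n_species))
  out
}

#' Parameters of the synthetic community generator
#'
#' The expected count of species *i* at sample *k* follows a Gaussian
#' niche-filtering kernel on one environment variable:
#' `log lambda_ik = log(baseline) - w * (e_k - o_i)^2 / (2 * niche_width^2)`,
#' where the species optimum `o_i` maps the species' (scaled) filter trait
#' affinely onto the observed range of the filter variable. `w = 0` is the
#' neutral model (environment-independent expectations). Counts are drawn
#' negative-binomial so the simulated data are overdispersed like real
#' arthropod counts.
#'
#' @param n_species pool size (must match the trait table used).
#' @param baseline_abundance expected count per sample at the niche optimum.
#' @param filtering_strength dimensionless filtering strength `w >= 0`.
#' @param niche_width niche breadth in the units of the filter variable.
#' @param nb_dispersion negative-binomial size parameter (> 0); smaller
#'   values give stronger overdispersion.
#' @param filter_trait trait whose scaled value sets the species optimum.
#' @param filter_env environment variable doing the filtering.
#' @return A validated list of class `"community_params"`.
#' @export
community_params <- function(n_species = 20, baseline_abundance = 24,
                             filtering_strength = 4, niche_width = 12,
                             nb_dispersion = 1,
                             filter_trait = "moisture_preference",
                             filter_env = "soil_moisture") {
  if (baseline_abundance < 0) stop("'baseline_abundance' must be nonnegative")
  if (filtering_strength < 0) stop("'filtering_strength' must be nonnegative")
  if (niche_width <= 0) stop("'niche_width' must be positive")
  if (nb_dispersion <= 0) stop("'nb_dispersion' must be positive")
  structure(as.list(environment()), class = "community_params")
}

#' Simulate a sample-by-species abundance matrix under trait filtering
#'
#' @param points a `sample_points` table (used for sample ids).
#' @param env environment table aligned with `points` (one row per point).
#' @param traits raw species-by-trait table covering all species.
#' @param params a [community_params()] object.
#' @param seed optional integer seed.
#' @return integer matrix (samples x species) of counts.
#' @seealso [community_params()] for the filtering model.
#' @export
simulate_community <- function(points, env, traits, params = community_params(),
                               seed = NULL) {
  if (!inherits(params, "community_params"))
    stop("'params' must be a community_params object")
  if (nrow(env) != nrow(points)) stop("'env' rows must align with 'points'")
  if (!params$filter_env %in% colnames(env))
    stop(sprintf("environment variable '%s' not found", params$filter_env))
  if (!params$filter_trait %in% colnames(traits))
    stop(sprintf("trait '%s' not found in the trait table", params$filter_trait))
  .set_seed(seed)

  scaled <- scale_trait_table(traits)
  xt <- scaled[, params$filter_trait]
  e <- env[[params$filter_env]]
  # species optima: affine map of the scaled filter trait onto the bulk
  # (5-95% quantile) span of the filter field, robust to moisture outliers
  qs <- quantile(e, c(0.05, 0.95), names = FALSE)
  o <- qs[1] + xt * (qs[2] - qs[1])

  lam <- params$baseline_abundance *
    exp(-params$filtering_strength * outer(e, o, "-")^2 / (2 * params$niche_width^2))
  counts <- matrix(rnbinom(length(lam), size = params$nb_dispersion, mu = lam),
                   nrow(lam), ncol(lam))
  dimnames(counts) <- list(
    if (!is.null(points$point_id)) points$point_id else rownames(points),
    rownames(traits))
  counts
}

#' Bundle aligned community-survey tables into one dataset
#'
#' @param points `sample_points` table.
#' @param env environment table (rows = points).
#' @param traits species-by-trait table (rows = species).
#' @param abundance samples-by-species count matrix.
#' @return list of class `"marsh_dataset"`.
#' @export
marsh_dataset <- function(points, env, traits, abundance) {
  abundance <- as.matrix(abundance)
  ids <- if (!is.null(points$point_id)) points$point_id else rownames(points)
  if (!identical(rownames(abundance), ids) || !identical(rownames(env), ids))
    stop("sample ids of points, env and abundance do not align")
  if (!all(colnames(abundance) %in% rownames(traits)))
    stop("trait table does not cover all species: ",
         paste(setdiff(colnames(abundance), rownames(traits)), collapse = ", "))
  structure(list(points = points, env = env, traits = traits,
                 abundance = abundance), class = "marsh_dataset")
}

#' @export
print.marsh_dataset <- function(x, ...) {
  cat(sprintf("marsh_dataset: %d samples, %d species, %d environment variables\n",
              nrow(x$abundance), ncol(x$abundance), ncol(x$env)))
  invisible(x)
}

#' Drop samples without any individuals
#'
#' Samples with zero total abundance carry no information for
#' relative-abundance analyses (diversity partitioning, CWM, Hellinger
#' ordination all require nonempty communities); this removes them from all
#' tables of a dataset, keeping rows aligned.
#'
#' @param dataset a [marsh_dataset()].
#' @return the dataset without empty samples; attribute `"empty_dropped"`
#'   lists the removed ids.
#' @export
drop_empty_samples <- function(dataset) {
  keep <- rowSums(dataset$abundance) > 0
  if (all(keep)) return(dataset)
  out <- dataset
  out$points <- dataset$points[keep, , drop = FALSE]
  class(out$points) <- class(dataset$points)
  out$env <- dataset$env[keep, , drop = FALSE]
  out$abundance <- dataset$abundance[keep, , drop = FALSE]
  attr(out, "empty_dropped") <- rownames(dataset$abundance)[!keep]
  out
}

#' Simulate a complete synthetic survey dataset
#'
#' End-to-end generator: nested design, environment fields, species pool and
#' filtered community, with optional sample loss. Three scenarios bundle the
#' generator settings used throughout the package's tests and documentation:
#' `"default"` (moderate filtering), `"neutral"` (`w = 0`), and
#' `"strong_filtering"` (`w = 10`, narrow niches). `paper_mimic = TRUE`
#' applies the full 215-point design and the 40 + 3 sample loss, leaving 172
#' samples.
#'
#' @param scenario one of `"default"`, `"neutral"`, `"strong_filtering"`.
#' @param seed master integer seed; stage seeds are derived from it.
#' @param n_nodes,n_infill design size (passed to [generate_nested_design()]).
#' @param field [field_params()] overrides.
#' @param community [community_params()] overrides (scenario sets
#'   `filtering_strength`/`niche_width` unless supplied here).
#' @param loss `c(n_lost, n_outliers)`; `NULL` keeps all samples.
#' @param paper_mimic logical; full design plus loss to 172 samples.
#' @return a [marsh_dataset()].
#' @export
simulate_dataset <- function(scenario = c("default", "neutral", "strong_filtering"),
                             seed = NULL, n_nodes = 12, n_infill = 23,
                             field = field_params(), community = NULL,
                             loss = NULL, paper_mimic = FALSE) {
  scenario <- match.arg(scenario)
  if (is.null(community)) {
    # baselines per scenario keep the expected total near ~195 individuals
    # per sample (the abundance scale of a well-populated salt-marsh plot)
    community <- switch(scenario,
      default = community_params(),
      neutral = community_params(filtering_strength = 0,
                                 baseline_abundance = 10),
      strong_filtering = community_params(filtering_strength = 10,
                                          niche_width = 8,
                                          baseline_abundance = 53))
  }
  if (paper_mimic && is.null(loss)) loss <- c(40, 3)
  seeds <- .derive_seeds(seed, 5L)
  pts <- generate_nested_design(n_nodes = n_nodes, n_infill = n_infill,
                                seed = seeds[[1]])
  env <- simulate_environment(pts, field, seed = seeds[[2]])
  traits <- simulate_trait_table(community$n_species, seed = seeds[[3]])
  ab <- simulate_community(pts, env, traits, community, seed = seeds[[4]])
  ds <- marsh_dataset(pts, env, traits, ab)
  if (!is.null(loss))
    ds <- apply_sample_loss(ds, n_lost = loss[1], n_outliers = loss[2],
                            seed = seeds[[5]])
  ds
}
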