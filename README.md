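# traitscape

Trait-based spatial analysis of small-scale community structure.

Soil communities — here, salt-marsh Collembola (springtails) sampled on a
nested design within a 35 m × 25 m plot — are structured both by local
environmental conditions (elevation, soil moisture, litter) and by the
spatial configuration of samples. `traitscape` implements the full
statistical workflow for asking, at that scale, *how much* each force
contributes and *which traits* it acts on:

* **Diversity partitioning** — Simpson species diversity and Rao's
  quadratic entropy `Q = Σᵢⱼ dᵢⱼ pᵢ pⱼ` for single- and multi-trait
  dissimilarities, partitioned additively into α (within-sample), β
  (turnover) and γ (pooled) components on the equivalent-number scale
  `1/(1−Q)`.
* **Dispersion null models** — identity randomisations that preserve
  per-sample richness and abundance distributions, with one-sided
  permutation tests for trait underdispersion (the signature of
  environmental filtering) and excess trait turnover.
* **Spatial predictors** — PCNM eigenfunctions (minimum-spanning-tree
  truncation, beyond-threshold distances set to 4t) and polynomial trend
  surfaces.
* **Ordination** — Hellinger transformation, (partial) redundancy
  analysis, permutation pseudo-F tests, permutation-based forward
  selection, and variation partitioning into pure environmental (E|S),
  shared (S∩E), pure spatial (S|E) and residual fractions.
* **CWM regressions** — community-weighted mean traits regressed on
  equal-count environmental and spatial predictor sets with sequential
  (Type-I) sum-of-squares decomposition.
* **Geostatistics** — empirical semivariograms, iterated-WLS fitting of
  spherical/exponential/Gaussian models in the practical-range
  convention, leave-one-out cross-validation model selection, and
  ordinary kriging with sectored nearest-neighbour search.
* **A synthetic-data generator** — the nested 215-point design,
  spatially autocorrelated environment fields, and trait-filtered,
  negative-binomial communities, so every statistic can be exercised and
  calibrated against data with known structure.

See `vignettes/traitscape-methods.Rmd` for the models, parameter
conventions and design decisions.

## Worked example

Simulate a full survey under strong moisture filtering — 215 design
points, 43 lost samples, ~195 individuals per sample — and partition its
diversity:

```r
library(traitscape)

ds <- drop_empty_samples(
  simulate_dataset("strong_filtering", seed = 7, paper_mimic = TRUE))
ds
#> marsh_dataset: 172 samples, 20 species, 6 environment variables

traits <- scale_trait_table(ds$traits)
diversity_partition_table(ds$abundance, traits)
#>                 facet gamma_eq pct_alpha pct_beta
#> 1             species    16.23      20.6     79.4
#> 2         multi_trait     1.61      80.9     19.1
#> 3         body_length     1.68      83.4     16.6
#> 4       antenna_ratio     1.46      89.9     10.1
#> 5           life_form     1.77      86.0     14.0
#> 6 moisture_preference     1.53      69.2     30.8
#> 7       habitat_width     1.63      84.8     15.2
```

Species turnover (79% of γ) far exceeds trait turnover (≤ 31% for any
trait facet): species replace each other across the plot, but largely by
others with similar traits. The identity null model shows why — local
communities hold less trait diversity, and samples differ more in traits,
than random identity draws would produce, i.e. environmental filtering:

```r
D <- trait_dissimilarity(traits)   # multi-trait Gower-mean dissimilarity
null_test(ds$abundance, D, "alpha_mean", n_reps = 499, seed = 1)
#> Null-model test of alpha_mean (equivalent scale, 499 replicates)
#>   observed = 1.3016  null mean = 1.3978  [2.5%, 97.5%] = [1.3851, 1.4098]
#>   p_low = 0.0020  p_high = 1.0000

null_test(ds$abundance, D, "beta_pct", n_reps = 499, seed = 2)
#> Null-model test of beta_pct (equivalent scale, 499 replicates)
#>   observed = 19.0613  null mean = 16.0004  [2.5%, 97.5%] = [15.0792, 16.9617]
#>   p_low = 1.0000  p_high = 0.0020
```

The spatial scale of the environment comes from the geostatistics module:

```r
co <- cbind(ds$points$x, ds$points$y)
emp <- empirical_semivariogram(co, ds$env$topography)
fits <- lapply(c("exponential", "spherical", "gaussian"),
               function(ty) fit_variogram(emp, ty))
cv <- loo_cross_validation(co, ds$env$topography, fits, k = 5)
cv$model
#> exponential variogram model: nugget = 0.002827, partial sill = 0.01852, range = 13.25
round(cv$rmse, 4)
#> exponential   spherical    gaussian
#>      0.0816      0.0817      0.0826
```

The fitted 13 m practical range reflects the nested structure of the
simulated topography (metre-scale microrelief under a broad cross-plot
gradient). `run_full_analysis(ds, seed = 1)` chains every stage —
preprocessing, partitioning, null tests, PCNM, forward selection,
variation partitioning, CWM regressions and variograms — into one
reproducible report, and `write_report()` serialises it to CSV tables.

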