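Package: traitscape
Title: Trait-Based Spatial Analysis of Small-Scale Community Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the small-scale spatial structure of
    trait-based community data, developed around salt-marsh Collembola
    (springtail) communities sampled on a nested, spatially explicit design.
    Provides additive partitioning of Simpson and Rao quadratic-entropy
    diversity into alpha, beta and gamma components on the
    equivalent-number (Jost) scale; identity-randomisation null models for
    trait under- and overdispersion; PCNM spatial eigenfunctions and
    polynomial trend surfaces; redundancy analysis with permutation
    pseudo-F tests, permutation-based forward selection and variation
    partitioning into pure environmental, pure spatial and shared
    fractions; community-weighted-mean trait regressions with sequential
    sums-of-squares decomposition; empirical semivariograms with weighted
    least-squares model fitting, cross-validation model selection and
    ordinary kriging; and a synthetic-data generator that emulates the
    nested survey design, spatially autocorrelated environment fields and
    trait-filtered overdispersed abundances the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
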