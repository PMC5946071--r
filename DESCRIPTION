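Package: methyldrift
Title: Age-Related Remodeling of the DNA Methylome and Calorie Restriction Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for age-related remodeling of bisulfite-sequencing
    DNA methylomes. Reads bismark-style coverage files, applies the common-site,
    coverage, shorth-variance, strand-aggregation and outlier/SNP filters used
    for RRBS site selection, fits per-site linear age regressions with
    confounders, selects nonlinear dynamics via an AIC grid of power and
    log transformations, computes per-sample Shannon entropy of the methylome,
    normalizes site trajectories for the average entropy effect (residual
    methylation fractions) and classifies sites relative to the entropy
    trajectory, summarizes region-level trends with z-scored slopes, Fisher
    enrichment and CpG-island removal tiers, and decomposes calorie-restriction
    effects into an initial shift and a cumulative time-after-treatment slope.
    A synthetic cohort generator with known ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    data.table,
    mgcv,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
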