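# methyldrift

Analysis of age-related remodeling of the DNA methylome from
bisulfite-sequencing count data, with a calorie-restriction (CR)
decomposition and a ground-truthed synthetic cohort generator.

The package is aimed at epigenomics analysts working with RRBS-style data
across an adult lifespan (per-CpG methylated/unmethylated read counts, one
coverage file per animal, plus a sample sheet with ages and treatment
groups) who want the standard aging-methylome quantities as tested, reusable
functions rather than one-off scripts.

## What it computes

**Site selection.** Common-site intersection, a soft coverage rule (drop a
site if more than 50% of the samples in any age group, or in the CR set,
have < 10× coverage), coverage-outlier masking, SNP exclusion, CpG strand
aggregation, and the *shorth* variance filter: sites are kept when their
across-sample SD reaches the mean of the shortest interval covering half of
all per-site SDs.

**Per-site age models.** OLS of methylation fraction *m* on age with
confounders; Benjamini–Hochberg FDR; and, for significant sites, AIC
selection over the transformation grid

> g(age) ~ m^p,  g ∈ {identity, ln},  p ∈ {−13, −5, −1, 1, 5, 13}

with a Jacobian correction making AICs comparable across response
transforms. Selected families map to dynamics labels: `(age, p ≤ −5)` →
late-life-accelerating, `ln(age)` → early-adulthood change, otherwise
linear.

**Entropy.** Normalized per-sample Shannon entropy
H = (1 / (N ln ½)) Σᵢ [mᵢ ln mᵢ + (1−mᵢ) ln(1−mᵢ)] ∈ [0, 1], its trajectory
over age (same transformation grid), and site-set permutation comparisons.

**Entropy normalization.** A penalized-spline GAM of slope against intercept
over significant sites gives each site an *expected* (entropy-driven) slope;
the residual methylation fraction RMF = OMF − age × expected slope is
refitted, and each site is classified as resist / follow / exceed / slower
/ counter relative to the entropy trajectory.

**Regions.** Half-open interval assignment (BED input), region trends as the
mean of z-scored member-site slopes with bootstrap CIs, two-sided Fisher
enrichment of gain/loss sites per region, CpG-island/shore/shelf removal
tiers, and strand-aware metagene profiles on the relative gene coordinate
(0 = TSS, 1 = gene end, extended one gene length both ways).

**CR decomposition.** Per site,
m = β₀ + β_age·age + β_IS·CR + β_TAT·(age − t0)·CR (+ confounders), so β_IS
is the initial shift at treatment start and β_TAT the cumulative per-month
effect; a 2-df nested F test, per-coefficient t tests, coefficient
correlations between aging and CR effects, and an oldest-age endpoint
comparison.

**Synthetic cohorts.** `cohort_design()` / `simulate_cohort()` generate an
RRBS-like cohort (16 age groups at 3–35 months, negative-binomial coverage,
binomial counts, bimodal baselines) from five trajectory families with known
per-site truth, including CR arms whose initial shift follows — and whose
cumulative effect opposes — each site's aging slope.

## Worked example

```r
library(methyldrift)

design <- cohort_design(n_sites = 2000, seed = 42)
cohort <- simulate_cohort(design)

pre  <- preprocess_sites(cohort$matrix, cohort$samples)
pre$report
#>   n_input_sites n_after_common n_after_coverage n_after_snp n_after_shorth
#> 1          2000           2000             1999        1701            533
#>   shorth_threshold
#> 1        0.1030878

fr   <- meth_fractions(pre$matrix)
fits <- fit_age_models(fr, cohort$samples)
table(fits$direction)
#> gain loss none
#>  205  179  149

ctrl <- cohort$samples$group == "control"
H  <- sample_entropy(fr)
ev <- entropy_vs_age(H[ctrl], cohort$samples$age[ctrl])
sprintf("entropy slope %.5f/month (p = %.2e)", ev$slope, ev$p)
#> [1] "entropy slope 0.00198/month (p = 7.75e-17)"

cr <- run_cr_analysis(fr, cohort$samples)
sprintf("r(aging, IS) = %.3f; r(aging, TAT) = %.3f",
        cr$correlations$age_is$r, cr$correlations$age_tat$r)
#> [1] "r(aging, IS) = 0.975; r(aging, TAT) = -0.976"
```

Reading the output: the shorth filter removes the near-constant majority of
sites (2000 → 533) and the age regression flags 384 of the remainder as
changing, split between gain and loss. Per-sample entropy rises
significantly with age — the methylome drifts toward intermediate
methylation. The CR coefficients show the generator's built-in structure:
the initial shift is aligned with each site's aging direction (r > 0) while
the cumulative time-after-treatment effect opposes it (r < 0), i.e. CR
slows methylome aging in this cohort.

`run_pipeline(design, out_dir)` chains every stage (including the coverage
file round trip, region enrichment on a synthetic annotation, and result
TSVs with a seed/configuration header); repeated runs with the same design
are byte-identical. A thin command-line wrapper with `simulate`, `pipeline`,
`preprocess` and `fit-age` subcommands is installed at
`inst/scripts/methyldrift-cli.R`.

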