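---
title: "Modeling age-related remodeling of the DNA methylome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling age-related remodeling of the DNA methylome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methyldrift)
```

# The scientific problem

Reduced representation bisulfite sequencing (RRBS) of blood across an
organism's adult lifespan yields, for every CpG site and every animal, a
methylated and an unmethylated read count. Most sites sit near fully
methylated or fully unmethylated; with age a minority of sites gain or lose
methylation, extreme methylation states drift toward intermediate levels
(the methylome's Shannon entropy rises), and lifespan-extending
interventions such as calorie restriction (CR) leave a signature that can be
decomposed into an instantaneous shift at treatment start and a cumulative
change accrued per month on treatment.

`methyldrift` implements this analysis chain as reusable, tested components:
site selection, per-site age regression with nonlinear-dynamics
classification, entropy trajectories, entropy normalization of site trends,
region-level summaries, and the CR decomposition — together with a synthetic
cohort generator with known ground truth, so that every stage can be
validated without any external download.

# The synthetic cohort generator

`cohort_design()` fixes the study conditions. The defaults emulate an aging
mouse blood cohort:

* 16 control age groups at 3–35 months (integer ages, 9 animals each), plus
  four CR groups at 10, 16, 21 and 27 months (9 animals each) treated from
  `t0 = 4` months. Integer control ages were chosen so that every CR group
  has an age-matched control group, which the endpoint comparison requires.
* per-entry read depth is negative binomial (mean 30, size 5, floored at one
  read), the methylated count binomial around the latent fraction jittered
  by truncated Gaussian noise (sd 0.02). A beta-binomial read model can be
  emulated by raising the jitter and lowering the dispersion size.
* a site-class mixture of 72% stable sites, 4% linear (`±0.005`
  fraction/month — a clearly resolvable but not dramatic effect at this
  sample size), 18% inverse-power-law sites, 3% logarithmic early-change
  sites and 3% entropy-drift sites. Stable and drift baselines are drawn
  from a U-shaped Beta so the marginal methylome is bimodal, as in real
  RRBS data.

Trajectory families (`site_class_spec()`):

| class | mean trajectory |
|---|---|
| `stable` | `m(age) = m0` |
| `linear` | `m0 + slope * age` |
| `late_accel` | inverse of `age = a + b * m^-13` (optionally mirrored `1 - m`) |
| `early_change` | `m0 + d * ln(age)` |
| `entropy_drift` | `0.5 + (m0 - 0.5) * exp(-kappa * age)` |

The `late_accel` family is parameterized by inverting the power-law
regression family itself, so model-selection tests ask the estimator to find
the true family among competitors rather than an approximation of it. The
mirrored form covers the gaining direction; note that the mirrored
trajectory is the reflection of the law, not itself a member of the fitted
family.

CR effects are applied per site as `is_shift + tat_slope * (age - t0)` for
treated samples at or past `t0`. By default the generator couples both
effects to the site's linearized aging slope — `is_shift = 6 * slope` and
`tat_slope = -0.4 * slope` plus small site-level noise — i.e. the initial
shift points in the direction of aging while the cumulative effect opposes
it. Tests that assert this sign structure therefore check estimation, not
discovery.

All randomness flows through deterministic per-site substreams of one cohort
seed: the same seed reproduces a cohort bit-identically, and a site's counts
do not depend on which other sites are generated.

**What the generator does not emulate:** genomic sequence context (CpG
density, chromosomes beyond interval arithmetic), read-level errors and
bisulfite conversion failure, cell-type composition shifts (these enter the
real analysis as user-supplied confounder columns), and correlated noise
between neighboring sites. Passing recovery tests on this generator
therefore demonstrates self-consistency of the estimators under the stated
noise model, not agreement with any particular real dataset.

# Site selection

`preprocess_sites()` chains five filters in a fixed order: common-site
intersection (a read in every sample), the soft coverage rule (drop a site
if more than 50% of the samples in any age group — or in the CR set,
evaluated as one extra group — have fewer than 10 reads; the 50% is a strict
inequality), coverage-outlier masking and SNP exclusion, strand aggregation,
and finally the shorth variance filter. The variance filter is applied last,
after aggregation, so that variance is measured on the final CpG-level
fractions.

The shorth threshold is the mean of the shortest window of `ceiling(n/2)`
sorted per-site standard deviations; window-width ties (within `1e-9`, which
also absorbs floating-point noise) are broken toward the lower-mean window,
making the threshold deterministic. Sites at exactly the threshold are kept.

Coverage outliers are entries above the per-sample 0.999 coverage quantile
*and* above twice the sample's median coverage. The second condition keeps
the rule from always clipping each sample's maximum — a pure quantile rule
marks the top entry of every sample as an outlier no matter how ordinary its
value. Masked entries count as unobserved, so a site masked anywhere is
subsequently dropped by the common-site rule; both knobs
(`cov_quantile`, `min_ratio`) are exposed.

# Per-site age models

Significance is decided on the untransformed linear model
(`fraction ~ age + confounders`, ordinary least squares, two-sided t test on
the age coefficient, Benjamini–Hochberg adjustment, `alpha = 0.05`). The
transformation grid is then fitted only to the significant sites to
characterize their dynamics. Deciding significance per best-AIC model would
add a selection bias; keeping the two steps separate makes the significant
fraction interpretable.

The grid fits every `g(age) ~ m^p` with `g` the identity or natural log and
`p` in `{-13, -5, -1, 1, 5, 13}`. Fractions are clipped to
`[1e-4, 1 - 1e-4]` before negative powers. `AIC = n log(RSS/n) + 2k`; when
the response is `ln(age)` the Jacobian term `2 * sum(log(age))` is added so
AIC values are comparable across response transforms (the uncorrected
comparison is available via `naive_aic = TRUE`). Candidates within
`ΔAIC < 2` of the minimum resolve toward the plain linear model. Dynamics
labels: response `age` with power `≤ -5` is late-accelerating, response
`ln_age` is early-change, everything else linear.

**A caveat on family recovery under predictor noise.** The grid regresses a
function of age on a transformed *noisy* methylation value. Noise `σ` on `m`
propagates into the response direction as roughly `13 |age - a| σ / m` for
the `m^-13` transform — tens of months somewhere along any trajectory
spanning a 32-month lifespan once `σ` reaches the percent scale. Strongly
curved transforms are therefore punished by predictor noise even when they
generated the data, and less-curved competitors win the AIC comparison. In
simulations the generating `(age, -13)` family is recovered essentially
always when the per-observation noise on `m` is at or below ~0.001, and
essentially never at `σ = 0.02`. This is a property of
errors-in-variables regression, not of the implementation; consumers should
read the dynamics labels on noisy data as a description of the best
*predictive* transform, not a certificate of the generating mechanism.

# Entropy and entropy normalization

Per-sample entropy is
`H = (1 / (N ln ½)) Σ_i [m_i ln m_i + (1 - m_i) ln(1 - m_i)]`, normalized so
`H = 1` when every site is at 0.5 and `H = 0` at the fully (un)methylated
extremes; fractions are clipped at `1e-6` before the logs so exact 0/1 sites
contribute 0 by continuity (RRBS fractions frequently are exactly 0 or 1).
The base of the logarithm cancels under the normalization. The entropy–age
trajectory reuses the same linear fit and transformation grid with `H` in
place of `m`. Permutation comparisons between site sets relabel *sites*
across the union (the compared unit is the site set); permuting samples
instead is available via `perm_unit = "samples"`.

Entropy normalization fits a penalized-spline generalized additive model of
the per-site slope against the per-site intercept over the significant sites
(basis dimension 20, smoothing by generalized cross-validation), evaluates
this expected slope for *all* sites (linear continuation beyond the fitted
intercept range, since spline extrapolation is unreliable), and subtracts
`age × expected slope` from the observed fractions to form residual
methylation fractions (RMF). RMF values may leave `[0, 1]` and are
deliberately not clipped. The RMF is refitted with the full age-model
machinery, and each site is classified by the significance pattern of the
two fits: `resist` (only RMF changes), `follow_entropy` (only the original
fraction changes), `stable` (neither), and for sites significant in both,
`exceed_entropy` / `slower_than_entropy` / `counter_entropy` by comparing
the observed slope's sign and magnitude against the expected slope. The
magnitude rule (`|observed| > |expected|` for exceed) is the minimal
consistent reading of "changed more/less than the average entropy".

**A statistical property worth knowing:** under an exact-cancellation null
(every site follows its expected slope precisely), the RMF test's
false-positive rate equals `alpha` when the expected-slope curve is flat,
but is *deflated* when the curve has a gradient: the OLS intercept estimate
is negatively correlated with the slope estimate, and that shared error
leaks through the smooth's gradient into the residual slope, shrinking its
variance below the fitted standard error. The effect is intrinsic to
intercept-indexed normalization, and it makes the resist/exceed/counter
calls conservative rather than anticonservative.

# Regions

Sites are assigned to labeled intervals by half-open overlap (GenomicRanges
under the hood; positions are 0-based half-open internally, converted from
the 1-based inclusive coverage-file dialect at the IO boundary only — one
documented conversion point prevents off-by-one drift). Region trends use
z-scored member-site fractions re-regressed on age and averaged per site
(each site weighs equally regardless of raw effect size); confidence
intervals come from a site-level bootstrap (1,000 resamples, fixed seed),
since member sites are spatially correlated and an analytic CI would
overstate precision. Direction enrichment uses the two-sided conditional
Fisher test computed from the hypergeometric probability-ordering rule
(vectorized in-package; it matches `stats::fisher.test` to numerical
precision, which the test suite asserts), with BH across regions within each
direction and the enrichment background being all tested post-filter sites.
CpG-island sensitivity tiers recompute the region slope after cumulatively
removing island, island+shore, island+shore+shelf members. Metagene profiles
map sites to the normalized gene coordinate (0 = TSS, 1 = gene end, extended
one gene length both ways, strand-mirrored) and smooth per-age-group mean
methylation along it with a GAM.

# Calorie-restriction decomposition

Per site, `m = β0 + β_age age + β_IS CR + β_TAT (age - t0) CR + confounders`
by OLS. Age enters untransformed and `t0` is subtracted only inside the
interaction, so `β_IS` is exactly the model's predicted CR-control
difference at the treatment-start age. The 2-degree-of-freedom nested F test
against the model without both CR terms flags sites where treatment has any
effect; per-coefficient t tests (BH-adjusted) separate initial-shift from
cumulative sites. Coefficient correlations (e.g. aging slope vs `β_IS`
among sites significant for both) use the control-only aging regression by
default; `aging_from = "joint"` substitutes the joint model's `β_age`. The
endpoint comparison contrasts mean methylation of the oldest CR group with
its age-matched control, per site, and correlates those differences with
control-cohort and CR-cohort aging slopes.

# Numerical choices and degenerate inputs

* All per-site regressions share one design matrix and are solved by one QR
  decomposition (no per-site `lm()` loops); a rank-deficient design is an
  error naming the collinear columns.
* Constant sites have slope 0 by convention (`0/0` guarded); RSS is floored
  at `1e-300` before logs in the AIC.
* Permutation p-values use the add-one estimator
  `(1 + #{|null| ≥ |obs|}) / (1 + n_perm)`, so they are never zero.
* Empty site sets, empty sample groups, zero-length genes, three-way strand
  collisions and malformed coverage lines raise informative errors rather
  than propagating NaN.
* Result TSVs carry a version/seed/configuration-hash header and no
  timestamps; identical inputs give byte-identical outputs.

# Problem sizes used by the test suite

The stochastic checks run on 10,000 sites × 144 control samples (plus 36 CR
samples) at coverage mean 30 — large enough that sensitivity, realized FDR,
category-recovery and null-calibration estimates have small Monte-Carlo
error, while a full suite completes in a couple of minutes on one CPU.
Oracle-equivalence checks (Fisher vs exhaustive enumeration over all 2×2
tables with margins ≤ 30, shorth vs quadratic scan on 1,000 vectors, BH vs
brute force over all orderings of six p-values) are exact-tolerance, not
statistical.

# Known limitations

* The generator's Gaussian jitter understates the overdispersion of real
  RRBS; effect-size calibration on real data should use the confounder
  machinery and its own coverage distribution.
* Dynamics classification under percent-scale noise favors less-curved
  transforms (see the errors-in-variables caveat above).
* The entropy permutation test assumes exchangeable sites within the pooled
  set; strong spatial correlation would make it anticonservative.
* Homolog vs species-specific comparisons expect user-supplied interval
  sets; no orthology computation is performed.
* Pathway/gene-set enrichment and cell-type deconvolution are out of scope;
  deconvolution estimates can be passed in as confounder columns.
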