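---
title: "Distance-based trait niches in monoculture-mixture designs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based trait niches in monoculture-mixture designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichekit)
```

## The scientific problem

When a plant species grows in a diverse mixture instead of monoculture, its
individuals plastically adjust traits related to light acquisition: shoots
elongate, leaves reorient, specific leaf area rises under shade. Such
intraspecific trait variation can move and reshape the species' *trait-based
niche* — its position and spread along axes defined by measured functional
traits — and thereby increase or decrease niche overlap with coexisting
species. `nichekit` quantifies these changes from shoot-level trait tables of
species sampled in monoculture and in a species-rich mixture, and links them
to species performance.

The basic observational unit is a single shoot, described by four
identifiers (species, block, plot, diversity level) plus 14 trait values in
three groups — height growth (shoot height and stretched length, internode
length, stem mass fraction), space filling (stem angles at base and in the
canopy, number of secondary axes, leaf number, maximum and minimum leaf
angle) and leaf morphology (leaf length and area, maximum and minimum
specific leaf area) — and shoot biomass as the performance variable.
Maximum/minimum leaf angles are derived as the extremes of per-segment
average angles over up to three vertical canopy segments (Q1 to Q3), and
SLA max/min as the extremes of per-segment SLA values; field angle
categories on the six-level ordinal scale are coded by their interval
midpoints (15, 45, ..., 165 degrees), the standard unbiased choice for
interval-censored classes.

## The niche statistics

All niche measures are Euclidean distances between shoots in standardized
trait space, computed per single trait axis and for the full 14-trait space:

* **niche density** — mean of all pairwise within-species distances in a
  diversity level. Smaller mean distance = denser packing; the statistic
  reported is the mean distance itself, so the interpretation is inverted.
* **niche width** — maximum pairwise within-species distance.
* **niche separation** — mean distance from the focal species' shoots to all
  heterospecific shoots at the same diversity level, all cross pairs pooled.
  The per-species-pair means are retained alongside, because "mean pairwise
  distance to other species" is ambiguous between pooling all pairs and
  averaging per-pair means; pooling is the primary definition here.
* **niche shift** — mean distance of each monoculture shoot to each mixture
  shoot of the same species, compared against the mean within-monoculture
  distance and reported as the log-response ratio
  `lrr = log(mean cross distance / mean within-monoculture distance)`.
  The natural log of the *ratio of the two means* is used (one value per
  species and trait set), not the mean of per-pair log ratios.
* **filling of trait space / trait range** — mean and maximum pairwise
  distance across all shoots of all species at one diversity level.

## Preprocessing chain

The pipeline order is fixed: `log_transform()` →
`block_correct()` → `standardize()`.

* Natural logs are applied to shoot length, internode length, leaf length,
  leaf area and SLA max/min; the two count traits (secondary axes, leaf
  number) use `log(x + 1)` so zero counts stay valid. The log base and the
  +1 offset for counts are package choices, documented so tests can be
  exact.
* Block correction is additive mean-centering per trait: value − block mean
  + grand mean. It preserves the grand mean exactly and equalizes block
  means; a mixed-model residual correction would be an alternative, but
  mean-centering is the simplest faithful reading of "corrected for block
  effects" and is exactly testable.
* Standardization is z-scoring with the *pooled* mean and sample (n − 1)
  standard deviation across both diversity levels and all species. Pooling
  is essential: monoculture and mixture positions must live on one common
  axis for shifts and width comparisons to be meaningful. A
  `per_diversity` scope is available for sensitivity analyses.
* Whether standardization precedes or follows block correction is not
  determined by the definitions; this package fixes correction first, then
  z-scoring. Pearson correlations for phenotypic integration are computed
  on log-transformed, block-corrected (unstandardized) data — r is
  invariant to the affine z-step, so this matches either reading.

Missing trait cells are allowed and propagate as per-trait-set complete-case
filtering: a shoot is excluded from a distance computation only if it lacks
one of the traits in the current trait set, which maximizes usable pairs per
axis.

## Phenotypic integration

Per species × diversity cell, Pearson correlations for all 91 unordered
pairs of the 14 traits are computed over shoots, with pairwise deletion
(pairs with fewer than 3 complete cases are unestimable and excluded from
the denominator). Integration is the count of pairs with raw p ≤ 0.05 — no
multiple-testing correction, because the count of raw-significant pairs is
itself the conventional integration measure — with a Holm-adjusted count
reported alongside for rigor.

## Inference chain

* **Trait responses.** Per trait, linear mixed models with random intercepts
  for block and plot are fitted by maximum likelihood in a nested fixed-
  effect sequence (null → species → diversity → species × diversity);
  likelihood-ratio Chi² tests assess each added term. Per-species
  monoculture-vs-mixture contrasts come from the REML full model via
  single-step multivariate-t adjustment (Holm as fallback). Grouping
  factors with fewer than two levels, or failed mixed fits, degrade to
  simpler models and are flagged in the output rather than erroring.
* **Reaction norms.** The slope of each z-scored trait on the two-level
  diversity coordinate (0 = monoculture, 1 = mixture) per species, which is
  exactly the difference of standardized cell means.
* **Tests on niche metrics.** A paired t-test across species compares niche
  width between levels; two-way ANOVAs with factors species and diversity
  (density, separation) or species and distance-set (shift) are run on the
  individual pairwise-distance observations. Distances sharing shoots are
  *not* independent, so these ANOVA p-values are anticonservative; the
  package therefore also provides a permutation p-value for the diversity
  main effect, obtained by permuting diversity labels within species and
  recomputing the F statistic. Both are reported; the permutation variant
  is the defensible one.
* **Diversity effect.** Per mixture shoot,
  `D = (BM_mix − mean BM_mono) / mean BM_mono`, the proportional deviation
  of mixture biomass from the species' monoculture mean; per species a
  one-sample t-test of D against 0. D is scale-invariant in biomass units.
* **Niche predictors of D.** Shoot-level mixed models with species identity
  as fixed effect and independent (crossed) random intercepts for plot and
  species; candidate predictors — niche identity (the shoot's standardized
  trait value), and per-shoot versions of density, separation and shift
  (the shoot's mean distance to, respectively, conspecific mixture shoots,
  heterospecific mixture shoots, and its species' monoculture shoots) — are
  added one at a time and assessed by AIC and likelihood-ratio test. The
  per-shoot mean-distance construction is the minimal refinement that
  brings the cell-level niche metrics to the resolution of the shoot-level
  model. Keeping species as both a fixed effect and a random intercept
  follows the stated model structure; the random species variance is then
  often estimated near zero, which is harmless for the fixed-predictor
  likelihood-ratio test.

## The synthetic-data generator

Because shoot-level field data of this kind are rarely shareable, every
stage is testable against a generator that emulates the structure of a
blocked monoculture-versus-mixture design: 7 legume-like species × 2
diversity levels × 10 shoots per cell (within the realistic 9–12 range), 4
blocks. Traits are drawn from a multivariate normal *on the analysis scale*
(log where the configuration says log), so programmed means, shifts and
covariances are exactly what the preprocessing chain sees; log-scale traits
are back-transformed for storage. Diversity-induced plasticity is an
additive analysis-scale shift of the mixture mean; block effects are
additive and identical across levels; biomass is lognormal with arithmetic
mean `(1 + δ) ×` the monoculture mean, so the programmed overyielding δ is
recovered without transformation bias. Draws outside physical bounds are
resampled (up to 100 attempts), not clipped, because clipping would distort
cell means.

One deliberate departure from strict field reality: shoots of every cell
are spread round-robin over all blocks (monoculture subplots per species ×
block, one mixture plot per block), rather than confining each species'
monoculture to a single plot in a single block. In the fully confounded
layout, block correction cannot be separated from species identity — for a
block containing only one species' monoculture, mean-centering erases that
species' trait signal entirely. The balanced layout gives the correction
step the structure it assumes, which is what parameter-recovery tests
require; the confounding of plots and species in real single-monoculture
designs remains a caveat for field data and is documented with the niche
metrics. Default trait means, SDs and biomass parameters are plausible
field magnitudes for temperate grassland legumes, chosen once (e.g. shoot
heights 25–80 cm, SLA 13–32 mm² mg⁻¹, biomass 0.6–3 g per shoot with
lognormal sdlog 0.3, analysis-scale trait SDs of 0.12–0.30 on log axes and
6–12 units on linear axes).

Preset scenarios fix the qualitative regimes: `null` (no plasticity, no
overyielding — every shift and D estimate centred on zero), `divergence`
(leaf-morphology mixture means pushed 0.6 analysis-scale units away from
the cross-species centre), `convergence` (height-growth mixture means
pulled 80% of the way to the tallest species), and `overyielding` (δ = 0.5
for the three tall/overyielding species, 0 for the rest).

What the generator does *not* emulate: the 60-species neighbourhood itself
(non-legume neighbours exist only implicitly through the plasticity
shifts), spatial transect geometry, non-normal trait distributions,
among-genet structure within species, and trait–biomass coupling beyond
what a user programs through the covariance. Passing recovery tests on
synthetic data therefore shows the estimators are consistent under the
assumed generative model, not that real communities satisfy the model.

## Numerical choices and degenerate inputs

* Sample (n − 1) SD everywhere; standardization post-conditions are
  enforced to 1e-10.
* Distance computations match a brute-force double-loop oracle to 1e-12;
  cross-set distances computed by the outer-product identity are clamped at
  zero to absorb negative round-off.
* Fewer than 2 usable shoots in a within-set call (or an empty cross set)
  yields an `NA` marker with a warning, never an exception; zero-variance
  traits error at standardization and are reported per-trait in the model
  chain without affecting other traits.
* `lrr` with a zero within-monoculture mean is `Inf` (or 0 when the cross
  mean is also zero); a paired t-test on identical widths returns t = 0,
  p = 1 rather than 0/0.
* All stochastic procedures (generation, permutations) take explicit seeds;
  identical seeds give byte-identical pipeline outputs.

## Problem sizes used in the shipped checks

The test-suite simulations use the default design (140 shoots) with 100
seeds for centring and recovery checks, 200 seeds for the type-I error
rates of the diversity likelihood-ratio test and the noise-predictor test
(accepted band 0.02–0.10 at α = 0.05), and 50 random tables of up to 30
records for the oracle equivalence; the acceptance script reruns the same
computations at 50 seeds for the centring/recovery summaries and 200 for
the type-I rates. These sizes give Monte-Carlo standard errors comfortably
below the decision thresholds.

## Known limitations

* The ANOVA on pairwise distances inherits the dependence problem noted
  above; use the permutation p-values for inference.
* Mean-centering block correction assumes block effects are additive on the
  analysis scale and that species composition is balanced across blocks; in
  confounded single-monoculture layouts it removes species signal.
* The niche metrics are point summaries of distance distributions; no
  kernel-density or hypervolume niche estimation, and no abundance
  weighting, is attempted.
* With only two diversity levels, "reaction norm" slopes are differences of
  means, not genuine dose-response curves.
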