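# nichekit

Trait-based niche analysis for monoculture–mixture biodiversity designs.

When plants grow in species-rich mixture instead of monoculture, their
individuals plastically adjust traits related to light acquisition — shoots
elongate, leaves reorient, specific leaf area changes. `nichekit` measures
how this intraspecific trait variation reshapes species niches, treating a
species' niche indirectly as its position and spread in standardized
functional-trait space, and links the changes to species performance. It is
aimed at community ecologists analysing shoot-level trait tables from
blocked monoculture-versus-mixture experiments (and at anyone wanting a
fully simulatable test bed for such analyses).

## The statistics at its core

All niche measures are Euclidean distances `d(x, y) = sqrt(Σ_t (x_t − y_t)²)`
between shoots in z-standardized trait space (per single trait axis and for
the full 14-trait set):

| measure | definition |
|---|---|
| niche density | mean within-species pairwise distance (small = densely packed) |
| niche width | maximum within-species pairwise distance |
| niche separation | mean distance to heterospecific shoots at the same diversity level |
| niche shift | `lrr = log(mean mono→mix distance / mean within-mono distance)` |
| filling / range | mean / maximum distance across all shoots of all species per level |

Phenotypic integration is the count of significant (raw p ≤ 0.05) Pearson
correlations among the 91 trait pairs per species × diversity level. The
diversity effect on performance is the proportional deviation
`D = (BM_mix − mean BM_mono) / mean BM_mono` per mixture shoot. An inference
chain provides mixed-model likelihood-ratio tests for trait responses
(random intercepts for block and plot; fixed sequence species → diversity →
interaction), reaction norms, paired-t/ANOVA/permutation tests on the niche
metrics, and AIC/LRT comparison of shoot-level niche predictors of D.

## Worked example

Simulate a trait-divergence scenario (mixture pushes species' leaf-trait
means apart), preprocess, and compute niche metrics:

```r
library(nichekit)

tab <- generate_traits(preset_scenario("divergence", seed = 42))
std <- preprocess(tab)   # log -> block-correct -> z-standardize
ns  <- niche_table(std, list(leaf_area = "leaf_area", multi = niche_traits()))

aggregate(separation ~ trait_set + diversity, data = ns$separation, FUN = mean)
#>  trait_set   diversity separation
#>  leaf_area     mixture  1.6111006
#>      multi     mixture  6.0676088
#>  leaf_area monoculture  0.7625284
#>      multi monoculture  4.6590662
```

Niche separation on the leaf-area axis roughly doubles in mixture
(1.61 vs 0.76 standardized units) — the programmed divergence — while the
multivariate separation moves less because the other 13 axes were not
shifted.

```r
aggregate(shift_lrr ~ trait_set, data = ns$shift, FUN = mean)
#>  trait_set shift_lrr
#>  leaf_area 0.9203410
#>      multi 0.1744127
```

The mean niche-shift log-response ratio of 0.92 on the leaf-area axis means
mono-to-mixture distances are `exp(0.92) ≈ 2.5` times the within-monoculture
distances: species moved their leaf-area niche. Under this scenario biomass
is not programmed to overyield, and the per-species diversity effect D is
correspondingly indistinguishable from zero:

```r
head(diversity_effect(tab)$species, 3)
#>  species  mean_D      t df     p  n
#>       Lp  0.0846  0.694  9 0.505 10
#>       Lc -0.0599 -0.740  9 0.478 10
#>       Mv -0.0229 -0.193  9 0.851 10
```

`run_pipeline()` glues all stages (niche metrics, integration counts,
trait LRT chain, metric tests, predictor models) and writes a CSV/JSON
bundle; `report()` prints a human-readable summary.

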