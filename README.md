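# threatscape

Integrated desk assessment of threats to tree species in data-poor tropical
regions. The package is aimed at conservation analysts who have presence-only
occurrence records, environmental raster layers, and a handful of national
pressure datasets, and need three linked products on a common 5-km grid:

1. **Ensemble species distribution models** — presence records are cleaned
   (collector/number deduplication, a <5 km georeferencing-uncertainty gate,
   one-record-per-cell spatial thinning), predictors are reduced (top-3
   temperature + top-3 precipitation bioclim variables by permutation
   importance, then iterative VIF elimination to VIF < 10), and pluggable
   learners are fitted over 3 pseudo-absence sets × replicate stratified
   70/30 splits. Single models are evaluated by rank-based AUC and the true
   skill statistic (TSS = sensitivity + specificity − 1); models with
   AUC ≥ 0.7 enter an unweighted mean-consensus ensemble, binarised at the
   10th percentile of suitability at the training presences.
2. **A cumulative threat index** — eight pressure factors (population
   density, cropland, roads, provincial overexploitation, tree-cover loss,
   burned-area trend, projected temperature and precipitation change), each
   standardised to 0–10 (e.g. population pressure
   `min(10, 10/log10(1001) · log10(density + 1))`, saturating at 1,000
   persons/km²), summed to a 0–80 index, classified Low / Moderate / High /
   Very high at the fixed 20/40/60 breakpoints, with urban cells masked out
   and *highest*/*lowest*-threat sensitivity scenarios bounding every
   threshold choice.
3. **Exposure overlays** — species richness maps, per-species area (km²) in
   each threat class, and protected-area coverage fractions by cell-centre
   membership.

A synthetic-data generator with fully known truth (autocorrelated predictor
fields, a species with a known logistic Gaussian niche, towns, roads,
provinces with harvest quotas, climate-change amplitude fields) makes the
entire pipeline testable offline; recovery of the generating niche is part
of the test suite. Rasters are exchanged as single-band ESRI ASCII grids and
vectors as GeoJSON — plain-text formats any GIS can read.

## Worked example

```r
library(threatscape)

cfg <- synthetic_config(seed = 7)          # 100x100 grid of 5-km cells, 150 presences
env <- gen_env_layers(cfg)                 # six autocorrelated predictors
sp  <- gen_species(cfg, env)               # presences from a known 2-variable niche
occ <- prepare_occurrences(sp$occurrences$records, cfg$grid)

pa   <- draw_pseudo_absences(cfg$grid, occ, seed = 7)   # 3 sets, 1/3 of background
runs <- fit_all(occ, env, pa, list(learner_glmnet(), learner_ranger()),
                n_replicates = 5, seed = 7)
ens  <- build_ensemble(runs)               # AUC >= 0.7 gate, mean consensus
ens
#> <ensemble_prediction> species: 24 member(s), AUC 0.693, TSS 0.274
bin  <- binarize_p10(ens, occ)

cor(as.vector(ens$mean_map$values), as.vector(sp$truth$probability_map$values),
    method = "spearman")
#> [1] 0.9615008
```

The ensemble suitability ranks cells almost identically to the generator's
true occurrence probability (Spearman ρ = 0.96), even though the pooled
held-out AUC is a modest 0.69 — with a widespread species, many
pseudo-absences fall in genuinely suitable habitat, which caps achievable
AUC without harming the recovered spatial pattern.

```r
f  <- gen_threat_factors(cfg)
tm <- threat_index_map(f, "reference")
tm
#> <threat_index_map> scenario 'reference', index range [18.6, 72.5]
sensitivity_compare(tm$classes, threat_index_map(f, "highest")$classes)$changed
#> [1] 23.78947

exposure_summary(bin, tm$classes, gen_protected_areas(cfg))
#> <exposure_summary> species: 23175 km2 suitable, 12.7% protected
#>   Low: 0.4%
#>   Moderate: 33.5%
#>   High: 63.4%
#>   VeryHigh: 2.6%
#>   Unclassified: 0.0%
```

Here 66% of the species' 23,175 km² suitable range sits in High or Very
high threat cells and 12.7% is protected; the `Unclassified` bucket holds
suitable cells masked as urban, so the class areas always sum to the total.
Tightening every factor threshold (the `highest` scenario) moves 23.8% of
cells up at least one threat class.
`run_pipeline(config)` chains all four stages from one YAML config and
writes a manifest with per-stage timings and output checksums; reruns with
the same config and seed reproduce identical digests.

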