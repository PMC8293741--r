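---
title: "Methods: ensemble distribution models and a cumulative threat index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble distribution models and a cumulative threat index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threatscape)
```

## Overview

`threatscape` implements an integrated desk assessment of threat to tree
species in data-poor regions. It has three analytical layers, all operating
on a common 5-km, cell-centre-registered analysis grid in a projected
equal-area CRS:

1. an **ensemble species distribution model (SDM)** turning cleaned
   presence-only records into a binary map of suitable habitat;
2. a **cumulative threat index** summing eight standardised anthropogenic
   and climatic pressure layers into a 0–80 score classified into four
   threat levels, with a scenario-based sensitivity analysis;
3. an **exposure overlay** quantifying how much of each species' suitable
   range falls in each threat class and inside protected areas.

A synthetic-data generator with fully known truth makes every stage
testable without any external download.

## The analysis grid and raster primitives

All layers are matrix-backed rasters on a `grid_spec` (rows × columns ×
cell size, north-west origin, row-major). We work on a planar equal-area
grid rather than in geographic degrees: at the 5-km resolution of the
method, planar distances and areas reproduce the procedure exactly and are
unit-testable without geodesy. Missing cells are explicit `NA`s and any
arithmetic with missing yields missing; the index summation is the single
documented exception (below). Resampling to the analysis grid uses the
cell-area-weighted mean (each target cell averages intersecting source
cells weighted by overlap area); cells with no non-missing overlap — e.g.
beyond a coastline — become missing and stay missing downstream. Buffers
are computed between cell centres, consistent with a raster pipeline;
users of vector buffers should expect half-cell differences at the edge of
a buffer band. Polygon membership (provinces, protected areas) is by
cell-centre containment under the even-odd rule, so overlapping reserve
polygons never double-count a cell.

File formats are deliberately plain: single-band ESRI ASCII grids for
rasters and GeoJSON for polygons/polylines, both self-describing text
formats readable by any GIS.

## Occurrence cleaning

Three steps, in order:

* **Duplicate removal** keys on collector + collection number (the same
  collection event deposited in several institutions), never on
  coordinates: two different gatherings at one locality are real data.
  Records lacking either field are never merged.
* **Uncertainty gate**: only records with *less than* 5 km of
  georeferencing uncertainty enter the models (strict inequality — a
  record whose uncertainty equals the cell size cannot be assigned to one
  cell). Records without uncertainty metadata are kept, loudly counted,
  because discarding them would throw away most historical data.
* **Spatial thinning** retains one record per 5 × 5 km cell to damp
  collection bias. "One per cell" alone is not deterministic, so for
  reproducibility we keep the record nearest the cell centre, ties broken
  by input order. Thinning is idempotent and the retained count equals the
  number of occupied cells.

## The ensemble SDM engine

The engine is deliberately learner-agnostic. The scientific contribution
of an ensemble platform is the orchestration — pseudo-absence handling,
replicate evaluation, gating, consensus — not any one algorithm, so
learners plug in behind a two-function adapter contract (`fit`,
`predict`, both seeded and deterministic). Two adapters ship: a
ridge-regularised logistic regression on linear + quadratic features (the
regression role; the quadratic terms let it express unimodal niche
responses) and a probability random forest (the machine-learning role,
the family that typically evaluates best on such data).

* **Pseudo-absences**: three independent sets, each sampling without
  replacement one-third of the eligible background cells (non-missing,
  not holding a presence). Multiple sets propagate background-sampling
  uncertainty into the ensemble. No exclusion buffer is drawn around
  presences; the sampling is plain random.
* **Replicates**: each learner × set is fitted on `n_replicates` fresh
  stratified 70/30 splits. Class imbalance is handled by weights (total
  presence weight = total pseudo-absence weight), not by resampling, so
  no records are duplicated or discarded. At full scale (5 learners ×
  3 sets × 100 replicates) this is 1,500 models per species; the package
  default for tests is 5 replicates, and the test suite documents the
  exact problem sizes it runs (100 × 100 grid, 150 presences, 2 × 3 × 5
  runs per seed).
* **Evaluation**: rank-based AUC (the Mann–Whitney probability that a
  presence outscores an absence, ties counting half) and the true skill
  statistic `TSS = sensitivity + specificity − 1` at the TSS-maximising
  threshold. The threshold is chosen by scanning midpoints of consecutive
  unique scores; among ties the lowest threshold wins (a fixed, documented
  tie-break — dialects differ here). Permutation importance is
  `1 − Pearson r` between predictions before and after shuffling one
  variable, averaged over the permutations and clipped to [0, 1]; a model
  with constant predictions gets importance 0 with a warning.
* **Ensemble**: members are the runs with held-out AUC ≥ 0.7 (inclusive);
  the consensus is the unweighted per-cell mean. Ensemble AUC/TSS are
  evaluated on the pooled held-out predictions of the members — the
  evaluation pool is not uniquely defined for a mean consensus, and
  pooling is the choice that uses every held-out point exactly once.
* **Binarisation**: the suitability threshold is the 10th percentile of
  ensemble suitability at the presence cells, computed with linear
  interpolation between order statistics (R quantile type 7; stated
  explicitly because percentile dialects differ), so at least 90% of the
  training presences fall inside the predicted range.

All randomness flows from one master seed through a recorded per-run seed
stream, so any run is bit-reproducible.

## Variable selection

Two stages mirror common SDM practice. First, to avoid overweighting the
19 correlated bioclimatic variables, only the three temperature-derived
and three precipitation-derived bioclim variables with the highest mean
permutation importance (from a reduced exploratory run) are retained;
non-bioclim variables (soil, elevation, radiation) pass through. Ties
break by BIO number for determinism. Second, iterative VIF elimination:
the variance inflation factor of each predictor is `1/(1 − R²)` from the
OLS regression of that predictor on all the others, the worst predictor is
removed (ties by name order), and the loop repeats until all VIFs fall
below 10. VIF is computed on the combined presence + pseudo-absence
sample — that is the data the models actually see; the alternative
(the full national grid) is defensible but answers a different question.

## The threat index

Eight factors are standardised to a 0–10 score and summed, so the index
spans 0 (no threats) to 80 (all threats at maximum):

| factor | scoring rule (reference scenario) |
|---|---|
| population density | `min(10, 10/log10(1001) × log10(d + 1))`, saturating at 1,000 persons/km² |
| cropland | 10 where cover ≥ 20%, else 0 |
| roads | 10 within 20 km of a primary/secondary road |
| overexploitation | 10 where a province's licensed volume > adequate volume |
| tree-cover loss | 10 where loss ≥ 20%, else 0 |
| burned-area trend | 10 on significant increasing-trend cells + 5-km buffer |
| temperature change | `min(10, |Δ|/2 °C × 10)`, multi-model mean minus current |
| precipitation change | `min(10, |Δ|/200 mm × 10)` |

The population coefficient is *derived from the saturation level*
(`10/log10(sat + 1)`) rather than hard-coded, so the score reaches exactly
10 at saturation under every scenario — the printed per-scenario
coefficients in our source material are mutually inconsistent with their
stated saturation levels (they are swapped), and deriving resolves this.

A factor that is missing in a cell contributes 0 to the sum there, with a
per-layer count reported: the index is defined as the sum of the factors
with national coverage, and poisoning the whole cell for one gap would
discard the other seven measurements. Urban cells are masked to missing
*after* summation — urban areas preclude natural vegetation entirely and
are excluded from both suitability and threat maps.

Classification uses fixed equal-width bands of the 0–80 range — Low
[0, 20), Moderate [20, 40), High [40, 60], Very high (60, 80] — not data
quantiles: the printed breakpoints are 20/40/60 regardless of the index
distribution. The boundary convention at 60 (High includes it) is the one
consistent with both "40–60" and ">60" labels; it is asserted in tests.

**Sensitivity scenarios.** Every threshold above is an expert choice, so
the index is re-built under a `highest` scenario (every threshold
stricter: saturation 800, cutoffs 15%, road buffer 25 km, quota −10%,
burn buffer 10 km, climate saturations 1.5 °C/150 mm) and a `lowest`
scenario (all looser: 1,200, 25%, 15 km, +10%, no buffer, 2.5 °C/250 mm).
Every factor score is monotone in its scenario parameter, so
highest ≥ reference ≥ lowest cellwise — a property the suite asserts.
`sensitivity_compare()` reports the percentage of cells (non-missing in
both maps, i.e. excluding urban) that changed class, split into increases
and decreases.

## Exposure and protection overlays

The richness map is the cellwise sum of the per-species binary maps. The
per-species `exposure_summary()` partitions the suitable range by threat
class (areas = cell count × 25 km²); suitable cells whose class is
missing (urban-masked) go into an explicit `Unclassified` bucket so the
partition always closes — fractions sum to 1 to 1e-9, asserted on every
call. Protection is the fraction of suitable cells whose centre lies in a
protected-area polygon, consistent with all other polygon handling.

## The synthetic study system

The generator's defaults define the study conditions used throughout the
tests: a 100 × 100 grid of 5-km cells (a country-scale extent at desk
scale), six environmental layers as standardised moving-average Gaussian
random fields with an autocorrelation range of 8 cells, a species with a
two-variable Gaussian niche (optima 0.5/−0.3, breadth 0.6 on the
standardised scale) at 15% prevalence, and 150 presence records — sample
sizes in the range of real herbarium datasets for widespread timber trees.
The intercept of the logistic niche is calibrated to the target prevalence
by root finding, so prevalence is exact by construction. Threat factors
are generated to *span their scoring scales*: town kernels exceed the
population saturation, the climate amplitude fields reach 125% of their
saturations, provincial licensed volumes range over 70–130% of the
adequate volume so every scenario margin bites somewhere. Provinces are a
jittered rectangular partition of the grid — simpler than Voronoi cells
and exactly rasterisable, which is what the tests need from them.

What the generator does **not** emulate: real coastline and the missing
data it creates, spatially structured georeferencing error, taxonomic
noise, and the strong road/city bias of real collections (a `road-biased`
sampling option exists but is off by default). Passing recovery tests
therefore demonstrates the correctness of the machinery, not field
performance on real occurrence data.

Recovery at the default conditions is strong by construction and verified
across 10 seeds: ensemble suitability correlates with the true occurrence
probability (Spearman ρ > 0.8), the two top-importance variables are the
true niche variables in at least 80% of seeds, and ≥ 90% of presence
cells fall inside the binarised range (a near-tautology of the
10th-percentile definition, asserted as a guard against threshold bugs).

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation (type 7). TSS threshold ties: lowest
  candidate, with a 1e-9 tolerance absorbing float noise between
  mathematically tied sensitivity/specificity sums.
* VIF: `Inf` is returned under perfect collinearity (R² = 1 within
  1e-12); a constant target column is an error, not a silent 0.
* AUC with a single score value on both sides is still defined (0.5);
  empty classes are errors.
* `buffer_mask(distance = 0)` and empty inputs are identity/no-ops, not
  errors, except where an empty input makes the statistic undefined
  (empty ensemble after gating, no suitable cells), which errors with the
  gate or cause named.
* Records outside the grid and rows touching missing predictor cells are
  dropped with counts — never silently.

## The pipeline and reproducibility

`run_pipeline()` executes prep → sdm → threat → exposure from a single
YAML-or-list config, writes every stage product to disk, and ends with an
atomically written manifest (config hash, master seed, versions, stage
timings, output checksums). A rerun with an identical config reuses the
cached model-stage rasters (keyed by the config hash) and reproduces
identical output digests; this is asserted in the test suite. The
functions, this config interface and the manifest *are* the package's
command-line story: an analysis is one `Rscript -e` away, and a shell
wrapper would add surface without adding capability.

## Known limitations

* Only two learner adapters ship; MARS- and MaxEnt-style learners must be
  supplied by the user behind the same contract.
* No spatial block cross-validation: replicate random splits share the
  spatial autocorrelation of the data, so AUCs are optimistic in the way
  standard random-split SDM evaluations are.
* The threat index measures exposure to pressure, not species' response
  to it; factors are summed unweighted.
* Reprojection is out of scope: all inputs must arrive in one projected
  CRS, and resampling requires matching CRS identifiers.
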