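---
title: "Evaluating an umbrella species: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating an umbrella species: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umbrellar)
```

Conservation funding is often organized around a single charismatic
"umbrella" species, on the premise that protecting its habitat shelters the
many species that co-occur with it. `umbrellar` implements a quantitative
evaluation of that premise. Given a set of co-registered species
distribution layers, a focal-area mask delineated for the umbrella species,
a protected-area mask and threat layers, it answers three questions:

1. **Coverage.** What share of each species' distribution falls inside the
   focal areas, and is that better than random placement of the same area?
2. **Efficiency.** How does the current protection estate compare with a
   multi-species prioritization covering the same total area?
3. **Threat.** Is the habitat inside focal areas more or less exposed to
   land-use conversion and invasion risk than the region as a whole?

Because the real inputs of such analyses are large external GIS products,
the package ships a synthetic-landscape generator that reproduces their
statistical structure at desk scale, with a truth record, so the entire
pipeline is exercisable and testable offline.

## The ranking model

The multi-species benchmark is a greedy complementarity ranking in the
style of the Zonation decision-support tool. Every conservation feature
$j$ (a species' seasonal distribution) is first normalized to per-cell
proportions $q_{ji}$ of its within-region distribution, so
$\sum_i q_{ji} = 1$. The landscape is then eroded one cell at a time:
at each step the cell with the smallest marginal loss $\delta_i$ is
removed, and removal order defines the rank map (first removed = rank
$1/N$, last = $1$). Two marginal-loss rules are implemented.

**Additive benefit (ABF, "richness")** sums power-transformed
representation losses across features:

$$\delta_i = \frac{1}{c_i} \sum_j \left[ (q_{jn})^z - (q_{jn-i})^z \right]$$

where $q_{jn}$ is the proportion of feature $j$ remaining in the landscape,
$q_{jn-i} = q_{jn} - q_{ji}$, $c_i$ is the cell cost, and $z = 0.25$ by
default. The concave transform means a feature reduced to little remaining
habitat dominates the sum, which mimics a species--area benefit curve;
species-rich cells are retained.

**Core-area (CAZ, "rarity")** scores a cell by the single feature that
would lose the largest share of its remaining distribution:

$$\delta_i = \frac{1}{c_i} \max_j \frac{q_{ji}}{q_{jn}}$$

so a cell holding the last stronghold of any feature scores 1 and is kept
to the very end, regardless of how the other features use it. The ratio is
defined as 0 for features with $q_{jn} = 0$ (a fully removed feature
contributes nothing, avoiding 0/0).

**Hierarchical removal masks** encode protection constraints: cells carry a
non-negative integer level and a level-$k$ cell is only considered for
removal once every level-$(k{-}1)$ cell is gone. Locking protected areas at
level 1 guarantees them the top ranks; the "outside focal" scenarios lock
protected and focal areas together, so the ranking orders only the
unprotected remainder. The four named scenarios map to (objective, mask)
pairs: richness/rarity lock protected areas; their `outside_focal`
variants lock protected and focal areas.

Cost is 1 everywhere by default -- ranking on biological criteria alone,
which is the right basis for comparing against focal areas that were
themselves delineated biologically -- but any positive cost layer is
accepted.

## Coverage and the equal-area comparison

Coverage of a region is simply $\sum_{i \in \text{region}} q_{ji}$. The
random baseline is analytic: if protection were placed uniformly at random,
expected coverage equals the region's share of analysis cells (the
generator's default focal share is 23.3%). A feature counts as
better-than-random only under strict inequality; a species counts as
covered if its best seasonal feature is. Both tallies are reported.

The equal-area comparison asks what a multi-species prioritization could
have achieved in the same area as the current estate (protected areas plus
focal areas): per feature, coverage by the current estate is paired with
coverage of the equally large top-ranked landscape fraction, and the mean
difference is tested with a two-sided paired t-test. When the rank map was
built with the current estate itself locked at the top level, the
top-ranked set *is* the current estate and the mean difference is zero to
numerical precision -- a self-consistency check in the test suite.

## Threat exposure

Threat masks come from two sources: projected land-cover layers (a habitat
cell is threatened if its future class is a conversion class -- cropland,
developed, forest encroachment, water) and an invasion-risk classification
(low resistance-and-resilience = high risk). Exposure of a feature is the
threatened share of its distribution. Inside focal areas the denominator is
the feature's within-focal mass, i.e. a conditional proportion, which makes
the inside and whole-region numbers directly comparable; a feature with no
mass inside focal areas is flagged and excluded from paired tests rather
than silently given 0. Every threat mask is applied to every feature
uniformly -- the analysis assumes all these species are harmed by direct
habitat loss, and encroachment classes are treated no differently from
anthropogenic conversion.

Summaries are produced at two levels. Feature level: exposures are averaged
over the land-use scenarios per feature, then within-focal is paired
against whole-region across features. Landscape level: the habitat-area
fraction threatened inside focal areas is paired against the whole-region
fraction across scenarios (df = scenarios − 1). Invasion risk is a
single-scenario threat and gets its own feature-level test and landscape
fractions, but no cross-scenario spread.

## The synthetic landscape generator

The generator is a stand-in for real distribution models, focal-area
shapefiles, land-use projections and invasion-risk maps -- not an
ecological model. Its construction is deliberately the simplest mechanism
with the right qualitative structure:

* **Random fields.** White noise smoothed with a truncated Gaussian kernel
  (SD = `autocorr_length` cells, edges renormalized) and standardized.
  Fields are contiguous and isotropic.
* **Species.** Species $s$ blends the umbrella field $U$ with an
  independent field $E_s$ as $a_s U + \sqrt{1 - a_s^2}\,E_s$, where
  $a_s \in [-1, 1]$ is the umbrella association, then thresholds at the
  species' drawn range-size quantile (log-uniform occupied fractions,
  default 1--60% of the landscape). Thresholding keeps the top-$k$ cells
  by exact count, so realized range sizes hit their targets to within one
  cell. Binary layers normalize to uniform weight over occupied cells;
  abundance-type species keep the continuous positive part above the
  threshold; seasonal species get a second winter layer from a
  torus-shifted copy of their field (partial spatial offset).
* **Focal areas** are the top quantile of the further-smoothed umbrella
  field over habitat cells -- contiguous, umbrella-rich patches hitting the
  target landscape share exactly (ties broken by a seeded shuffle).
  Protected areas are the top quantile of an independent field: placed
  without regard to the umbrella, overlap with focal areas allowed.
* **Threats.** Per scenario, a risk field with shorter correlation length
  (conversion is patchier than species ranges) is shifted by
  `threat_bias` field-SD inside focal areas and thresholded to the target
  threatened fraction. Negative bias pushes threats away from focal areas.
  Threatened cells are also written into projected land-cover layers (and
  the invasion-risk classes) so the class-based threat operations are
  exercised end to end.
* **Baseline land cover** assigns contiguous non-habitat patches
  (forest/water/cropland/developed, default 15% of cells) whose exclusion
  yields the analysis mask. Aggregation happens before exclusion when
  coarsening real inputs: the analysis mask lives on the working grid so
  every layer shares one grid.

Default study conditions (chosen once, as the conditions the analysis
emulates): 100 × 100 cells at a nominal 270 m, 25 species giving 30
features (5 seasonal pairs, 3 abundance-type), focal share 23.3%,
protected share 15.6% -- so the expected protected-or-focal union is about
35%, since the two are placed independently -- four land-use scenarios at
11.5% threatened habitat each, invasion risk at 23.9%, and
`threat_bias = -0.4` SD, which under the Gaussian threshold construction
roughly halves threat prevalence inside focal areas (about 5--6% versus
11.5%), the contrast the analysis is designed to detect. Associations are
drawn uniformly from [-0.3, 0.9]: most species share the umbrella's
habitat, a few avoid it. All generators are pure functions of the
configuration and a master seed (per-stage seeds are derived arithmetic
offsets), so every layer is bit-reproducible.

What the generator does **not** emulate: distribution-model error and
spatial uncertainty, nested habitat specialization (associations are
pairwise with one umbrella field only), anisotropy, temporal dynamics, and
any calibration to real shrub-steppe data. Passing recovery tests therefore
show the pipeline's statistics respond correctly to known structure, not
that real landscapes behave this way.

## Numerical choices

* **Tie-breaking.** Equal marginal losses are resolved by removing the
  lowest row-major cell index first. Rankings are fully deterministic;
  cells worthless to every feature ($\delta_i = 0$) leave first within
  their mask level.
* **Incremental state.** $q_{jn}$ is updated by subtraction as cells are
  removed, clamped at 0, and recomputed from scratch (extended-precision
  accumulation) every 1,000 removals to bound floating-point drift; the
  state invariant $q_{jn} = \sum_{i \in \text{remaining}} q_{ji}$ is
  enforced to 1e-9, and a deficit beyond that tolerance is a hard error,
  not a warning. The compiled core and the naive R reference start from
  the same R-computed totals so the two routes are bit-identical at
  `warp = 1`.
* **Warp.** Removing `warp` > 1 cells per evaluation approximates the
  exact greedy ranking; the default is 1 and the reference implementation
  only supports 1.
* **Degenerate inputs.** Features that are all-zero or all-nodata on the
  analysis mask raise an error (or are dropped explicitly with
  `drop_empty = TRUE` -- never kept silently). An empty analysis mask is an
  error. A paired test on identical non-zero differences is undefined and
  raises; all-zero differences return t = 0, p = 1 by convention.
* **Feature normalization** divides by the in-mask total and renormalizes
  once more, so sums are 1 to well below the 1e-9 tolerance regardless of
  input scale.
* **Coverage at a fraction** selects cells with rank fraction strictly
  above $1 - f$ with a 1e-12 guard, so a fraction equal to $m/N$ selects
  exactly the $m$ last-removed cells.
* **Inclusion thresholds.** The two-criterion screen keeps a species if
  its range covers at least 20% of the region (inclusive) or if strictly
  more than 20% of its entire distribution lies inside the region -- the
  asymmetry is deliberate and tested.

## Problem sizes in the test suite

The suite runs entirely on generated data: oracle-equivalence and
invariant checks on random stacks of up to 100 cells and 5 features (20
seeds, both objectives, with and without masks); recovery checks on the
default 100 × 100 conditions over 20 seeds; and the null calibration of
the exposure test on 60 × 60 landscapes with 16 species over 200 seeds.
These sizes were chosen so the properties under test are well resolved
while the whole suite stays quick to run.

## Known limitations

* **Correlated features and the paired t-test.** All features on one
  landscape share the same threat realization, so their focal-versus-region
  exposure differences carry a common shock: whether a particular threat
  field happened to fall inside or outside the focal areas moves every
  feature together. The cross-feature paired t-test assumes independent
  differences and therefore over-rejects under the null; the suite
  measures this directly (unbiased threats, 200 seeds) and the measured
  rejection rate is far above the nominal 5%. The scenario-level test on
  landscape fractions (df = scenarios − 1) does not pool correlated
  features and is the more trustworthy headline statistic; the same caveat
  applies to any cross-species t-test computed on a single shared
  landscape, including published ones. A block-resampling or
  random-effects formulation would be the principled fix and is out of
  scope here.
* **No reprojection.** Inputs must be pre-aligned on one grid; only block
  aggregation (maximum rule, partial edge blocks allowed) is provided.
  Focal-area boundaries must arrive pre-rasterized.
* **Raster format.** Layers are read and written as single-band ESRI ASCII
  grids -- plain text, exact round-trip, interoperable with standard GIS
  tools -- with 0/1 masks (nodata 255) and integer-level removal masks.
* **Scope.** No boundary-length penalties, connectivity transforms,
  condition layers or administrative units; no species-specific threat
  responses; no climate projection. The ranking reproduces the two
  objective functions above, nothing more.
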