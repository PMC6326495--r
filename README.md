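# umbrellar

Does protecting one flagship species protect everything that lives beside
it? `umbrellar` is an R package for evaluating an **umbrella species**
strategy quantitatively: it measures how well focal conservation areas
delineated for a single species cover the distributions of co-occurring
species, how that coverage compares with a random-placement baseline and
with equal-area **multi-species prioritizations**, and whether habitat
inside the focal areas is more or less exposed to landscape threats
(land-use conversion, annual-grass invasion) than the region as a whole.
It is aimed at conservation planners and macroecologists who want to run
or stress-test this style of surrogacy analysis without a GIS stack: all
inputs are plain rasters, and a synthetic-landscape generator reproduces
their statistical structure at desk scale.

## The model at the core

Each conservation feature *j* (a species' seasonal distribution) is
normalized to cell proportions *q<sub>ji</sub>* summing to 1 over habitat
cells. The multi-species benchmark is a greedy complementarity ranking
(Zonation-style): cells are removed one at a time, always the one with the
smallest marginal loss δ<sub>i</sub>, and removal order gives every cell a
rank. Two objectives are implemented:

* **Additive benefit (richness)** — with *q<sub>jn</sub>* the proportion
  of feature *j* still remaining and cost *c<sub>i</sub>*:

  δ<sub>i</sub> = (1/c<sub>i</sub>) Σ<sub>j</sub> [ (q<sub>jn</sub>)<sup>z</sup> − (q<sub>jn</sub> − q<sub>ji</sub>)<sup>z</sup> ],  z = 0.25

* **Core-area (rarity)** — the worst-hit feature decides:

  δ<sub>i</sub> = (1/c<sub>i</sub>) max<sub>j</sub> q<sub>ji</sub> / q<sub>jn</sub>

Hierarchical removal masks lock protected areas (and optionally the focal
areas) into the top ranks. Coverage statistics, the analytic random
baseline (the focal share of habitat cells), paired t-tests for the
equal-area comparison, and conditional threat-exposure summaries complete
the pipeline. The greedy core is compiled (Rcpp); a naive R reference
implementation serves as its exact oracle in the tests.

## Worked example

The `analysis/` directory holds the four-stage workflow; each stage is a
thin driver over package functions. Stage 1 simulates the default study
conditions (100 × 100 cells, 25 species / 30 features, focal areas on the
top 23.3% of the umbrella's distribution, threats biased 0.4 SD away from
them):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_prioritize.R
Rscript analysis/03_coverage.R
Rscript analysis/04_threats.R
```

Stage 3 prints, for seed 1:

```
random baseline (focal fraction): 23.3%
mean feature coverage by focal areas: 38.2%
features above random: 18 of 30 (60%)
species above random: 17 of 25 (68%)
prioritize_richness: current 46.4% vs prioritized 62.8% (diff +16.3 pp, t = 3.25, df = 29, p = 0.00291)
prioritize_rarity: current 46.4% vs prioritized 61.5% (diff +15.1 pp, t = 2.66, df = 29, p = 0.0125)
```

Reading: the umbrella's focal areas cover on average 38.2% of each
feature's distribution — well above the 23.3% a random placement would
give — and 17 of the 25 species do better than random (the generator
plants a minority of species that avoid the umbrella's habitat, and those
correctly fall below the baseline). A free multi-species prioritization
over the same total area would lift mean coverage by ~15–16 percentage
points, the price of anchoring protection to one species. Stage 4 prints
the threat side:

```
land-use change: 5.8% (+/- 1.7 SE) of habitat threatened inside focal areas vs 11.5% (+/- 0.0) across the region
  scenario-level paired t: mean diff -5.7 pp, t = -3.30, df = 3, p = 0.0457
cheatgrass invasion risk: 11.9% of habitat inside focal areas vs 23.9% across the region
```

i.e. the generator's planted avoidance of focal areas by threats (bias
−0.4 SD) is recovered: habitat inside focal areas is about half as
threatened as the region-wide 11.5%.

The same machinery is available directly:

```r
library(umbrellar)
sim <- simulate_landscape(sim_config(seed = 1))
rank <- rank_landscape(sim$stack, prioritizer_config("CAZ"),
                       build_removal_mask("prioritize_rarity",
                                          sim$protected, sim$focal))
coverage_at_fraction(rank$rank_map, sim$features, 0.233)
```

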