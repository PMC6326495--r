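#!/usr/bin/env Rscript

## Stage 1: generate the synthetic study landscape.
##
## Builds the default study conditions -- a 100 x 100 habitat grid with 25
## species (30 conservation features: 5 seasonal pairs, 3 abundance-type),
## focal areas carved from the top 23.3% of the umbrella species'
## distribution, protected areas on 15.6%, four land-use change scenarios
## touching 11.5% of habitat each and an invasion-risk layer on 23.9%, with
## threats biased 0.4 SD away from focal areas -- and writes every input
## layer to results/01_sim_inputs/ for the later stages.

suppressPackageStartupMessages(library(umbrellar))

seed <- 1
outdir <- file.path("results", "01_sim_inputs")

config <- sim_config(seed = seed)
sim <- simulate_landscape(config)
write_simulation(sim, outdir)

cat(sprintf("landscape: %d x %d cells, %d habitat (%.1f%%)\n",
            config$n_rows, config$n_cols, mask_size(sim$analysis),
            100 * mean(sim$analysis$member)))
cat(sprintf("features: %d (from %d species)\n", length(sim$features),
            config$n_species))
cat(sprintf("focal areas: %.1f%% of habitat (target 23.3%%)\n",
            100 * sim$truth$realized_focal_fraction))
cat(sprintf("protected areas: %.1f%% of habitat\n",
            100 * sim$truth$realized_protected_fraction))
cat(sprintf("umbrella associations: %d positive, %d negative\n",
            sum(sim$truth$species$umbrella_assoc > 0),
            sum(sim$truth$species$umbrella_assoc < 0)))
cat(sprintf("inputs written to %s\n", outdir))
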