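#!/usr/bin/env Rscript

## Stage 4: threat exposure inside focal areas versus the whole region.
##
## Derives threat masks from the projected land-cover layers (conversion
## classes on habitat cells) and the invasion-risk classes (low resistance/
## resilience = high risk), computes each feature's exposure inside focal
## areas and across the region, and summarizes with paired t-tests at the
## feature level (scenario-averaged) and at the landscape level (across the
## four scenarios). Tables go to results/04_threats/.

suppressPackageStartupMessages(library(umbrellar))

indir <- file.path("results", "01_sim_inputs")
outdir <- file.path("results", "04_threats")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

stack <- read_stack(file.path(indir, "features.csv"),
                    file.path(indir, "analysis_mask.asc"),
                    file.path(indir, "focal_mask.asc"),
                    file.path(indir, "protected_mask.asc"),
                    drop_empty = TRUE)
analysis <- stack$analysis_mask
focal <- stack$focal_mask

conversion_classes <- c(11, 21, 22, 23, 24, 41, 42, 43, 81, 82)
scenario_ids <- c("A1B", "A2", "B1", "B2")
threats <- lapply(scenario_ids, function(sid)
  lulc_threat_mask(read_raster(file.path(indir,
                                         paste0("lulc2050_", sid, ".asc"))),
                   conversion_classes, analysis, sid))
threats <- c(threats,
             list(cheatgrass_risk_mask(
               read_raster(file.path(indir, "resistance_resilience.asc")),
               analysis)))

exposures <- exposure_table(stack$features, threats, focal)
write.csv(exposures, file.path(outdir, "threat_exposure.csv"),
          row.names = FALSE)
s <- scenario_summary(exposures, threats, focal, analysis)

lulc <- s$lulc
cat(sprintf("land-use change: %.1f%% (+/- %.1f SE) of habitat threatened inside focal areas vs %.1f%% (+/- %.1f) across the region\n",
            100 * lulc$mean_landscape_exposure_focal,
            100 * lulc$se_landscape_exposure_focal,
            100 * lulc$mean_landscape_exposure_region,
            100 * lulc$se_landscape_exposure_region))
st <- lulc$scenario_test
cat(sprintf("  scenario-level paired t: mean diff %+.1f pp, t = %.2f, df = %d, p = %.3g\n",
            100 * st$mean_difference, st$t_statistic,
            st$degrees_of_freedom, st$p_value))
ft <- lulc$feature_test
cat(sprintf("  species-level (scenario-averaged): %.1f%% inside vs %.1f%% region (t = %.2f, df = %d, p = %.3g)\n",
            100 * mean(lulc$feature_means$exposure_focal),
            100 * mean(lulc$feature_means$exposure_region),
            ft$t_statistic, ft$degrees_of_freedom, ft$p_value))

cheat <- s$cheatgrass
cat(sprintf("cheatgrass invasion risk: %.1f%% of habitat inside focal areas vs %.1f%% across the region\n",
            100 * cheat$mean_landscape_exposure_focal,
            100 * cheat$mean_landscape_exposure_region))
cft <- cheat$feature_test
cat(sprintf("  species-level: %.1f%% inside vs %.1f%% region (t = %.2f, df = %d, p = %.3g)\n",
            100 * mean(cheat$feature_means$exposure_focal),
            100 * mean(cheat$feature_means$exposure_region),
            cft$t_statistic, cft$degrees_of_freedom, cft$p_value))

for (tid in names(s))
  write.csv(s[[tid]]$per_scenario,
            file.path(outdir, paste0("summary_", tid, ".csv")),
            row.names = FALSE)
cat(sprintf("exposure tables written to %s\n", outdir))
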