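#!/usr/bin/env Rscript

## Stage 3: how well do the umbrella's focal areas cover the other species?
##
## Per-feature overlap with focal areas against the random-placement
## baseline (the focal landscape fraction), and the equal-area comparison:
## current protection (protected areas + focal areas) versus what the
## richness- and rarity-based prioritizations of stage 2 would cover in the
## same total area, paired t-test across features. Tables go to
## results/03_coverage/.

suppressPackageStartupMessages(library(umbrellar))

indir <- file.path("results", "01_sim_inputs")
rankdir <- file.path("results", "02_prioritization")
outdir <- file.path("results", "03_coverage")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

stack <- read_stack(file.path(indir, "features.csv"),
                    file.path(indir, "analysis_mask.asc"),
                    file.path(indir, "focal_mask.asc"),
                    file.path(indir, "protected_mask.asc"),
                    drop_empty = TRUE)

cov <- coverage_vs_random(stack$features, stack$focal_mask,
                          stack$analysis_mask)
write.csv(cov$records, file.path(outdir, "coverage_records.csv"),
          row.names = FALSE)
cat(sprintf("random baseline (focal fraction): %.1f%%\n",
            100 * cov$summary$baseline))
cat(sprintf("mean feature coverage by focal areas: %.1f%%\n",
            100 * mean(cov$records$overlap)))
cat(sprintf("features above random: %d of %d (%.0f%%)\n",
            cov$summary$n_features_above, cov$summary$n_features,
            100 * cov$summary$frac_features_above))
cat(sprintf("species above random: %d of %d (%.0f%%)\n",
            cov$summary$n_species_above, cov$summary$n_species,
            100 * cov$summary$frac_species_above))

## coverage medians by season group
season_groups <- vapply(stack$features, function(f) f$season_tag,
                        character(1))
names(season_groups) <- feature_ids(stack)
med <- group_summary(cov$records, season_groups)
cat("median coverage by season group:",
    paste(sprintf("%s %.1f%%", names(med), 100 * med), collapse = ", "),
    "\n")

## equal-area comparison against the stage-2 prioritizations
current <- mask_union(stack$protected_mask, stack$focal_mask,
                      "current_protection")
summary_rows <- NULL
for (sc in c("prioritize_richness", "prioritize_rarity")) {
  rank_map <- read_rank_map(file.path(rankdir, paste0("rank_", sc, ".asc")))
  eq <- equal_area_comparison(stack$features, current, rank_map,
                              stack$analysis_mask)
  write.csv(eq$table, file.path(outdir, paste0("equal_area_", sc, ".csv")),
            row.names = FALSE)
  cat(sprintf("%s: current %.1f%% vs prioritized %.1f%% (diff %+.1f pp, t = %.2f, df = %d, p = %.3g)\n",
              sc, 100 * mean(eq$table$current_coverage),
              100 * mean(eq$table$prioritized_coverage),
              100 * eq$test$mean_difference, eq$test$t_statistic,
              eq$test$degrees_of_freedom, eq$test$p_value))
  summary_rows <- rbind(summary_rows,
                        data.frame(scenario = sc, fraction = eq$fraction,
                                   mean_current = mean(eq$table$current_coverage),
                                   mean_prioritized = mean(eq$table$prioritized_coverage),
                                   mean_difference = eq$test$mean_difference,
                                   t = eq$test$t_statistic,
                                   df = eq$test$degrees_of_freedom,
                                   p = eq$test$p_value))
}
write.csv(summary_rows, file.path(outdir, "equal_area_summary.csv"),
          row.names = FALSE)
cat(sprintf("coverage tables written to %s\n", outdir))
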