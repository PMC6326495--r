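PIPELINE_SCENARIOS <- c("prioritize_richness", "prioritize_rarity",
                        "prioritize_richness_outside_focal",
                        "prioritize_rarity_outside_focal")

## land-cover class codes treated as habitat conversion
LULC_THREAT_CLASSES <- c(11, 21, 22, 23, 24, 41, 42, 43, 81, 82)

#' Objective function of a named scenario
#'
#' @param scenario One of the four pipeline scenario names.
#' @return `"ABF"` for richness scenarios, `"CAZ"` for rarity scenarios.
#' @export
scenario_objective <- function(scenario) {
  if (!scenario %in% PIPELINE_SCENARIOS)
    uml_stop(sprintf("unknown scenario '%s'", scenario), "config_error")
  if (grepl("richness", scenario)) "ABF" else "CAZ"
}

#' Removal mask for a named scenario
#'
#' Richness/rarity scenarios lock protected areas into the top ranks
#' (removal level 1); the outside-focal scenarios lock protected areas and
#' focal areas (both level 1), so the ranking orders only the unprotected
#' remainder. Missing masks contribute nothing.
#'
#' @param scenario One of the four pipeline scenario names.
#' @param protected,focal Optional [region_mask()]s.
#' @param grid A [grid_spec()] (required if both masks are `NULL`).
#' @return A [removal_mask()].
#' @export
build_removal_mask <- function(scenario, protected = NULL, focal = NULL,
                               grid = NULL) {
  if (!scenario %in% PIPELINE_SCENARIOS)
    uml_stop(sprintf("unknown scenario '%s'", scenario), "config_error")
  if (is.null(grid))
    grid <- if (!is.null(protected)) protected$grid
    else if (!is.null(focal)) focal$grid
    else uml_stop("no grid available for the removal mask", "config_error")
  level <- matrix(0L, grid$n_rows, grid$n_cols)
  if (!is.null(protected)) {
    check_same_grid(protected$grid, grid, "protected mask and grid")
    level[protected$member] <- 1L
  }
  if (grepl("outside_focal", scenario) && !is.null(focal)) {
    check_same_grid(focal$grid, grid, "focal mask and grid")
    level[focal$member] <- 1L
  }
  removal_mask(level, grid)
}

#' Union of two region masks
#' @param a,b [region_mask()]s on one grid.
#' @param mask_id Identifier for the union.
#' @return A [region_mask()].
#' @export
mask_union <- function(a, b, mask_id = paste(a$mask_id, b$mask_id, sep = "+")) {
  check_same_grid(a$grid, b$grid, "masks")
  region_mask(a$member | b$member, a$grid, mask_id)
}

#' Run the full evaluation pipeline on a synthetic landscape
#'
#' Simulates a landscape, evaluates per-feature coverage of the focal areas
#' against the random baseline, ranks the landscape under the requested
#' scenarios, compares current protection (protected areas plus focal
#' areas) with each equal-area prioritization, and summarizes threat
#' exposure inside focal areas versus the whole region. All tables are
#' written under `outdir` together with a checksummed output manifest and a
#' run log recording the configuration; runs are deterministic for a fixed
#' config.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @param scenarios Character vector of scenario names (subset of the four;
#'   empty for a coverage-only run).
#' @param z_exponent,warp Prioritizer settings (see [prioritizer_config()]).
#' @param write_rank_maps Write per-scenario rank maps as ASCII grids.
#' @return A list: `sim`, `coverage`, `scenario_results` (per scenario:
#'   config, rank result, equal-area comparison where applicable), `threat`
#'   (exposure table and summary), `files` (output manifest data frame).
#' @export
run_pipeline <- function(config, outdir,
                         scenarios = PIPELINE_SCENARIOS,
                         z_exponent = 0.25, warp = 1L,
                         write_rank_maps = TRUE) {
  stopifnot(inherits(config, "uml_simcfg"))
  bad <- setdiff(scenarios, PIPELINE_SCENARIOS)
  if (length(bad))
    uml_stop(sprintf("unknown scenario(s): %s", paste(bad, collapse = ", ")),
             "config_error")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("umbrellar pipeline run, seed %d", config$seed),
                 paste0("config: ",
                        jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                         null = "null")))

  sim <- simulate_landscape(config)
  outputs <- character(0)
  put <- function(path) { outputs <<- c(outputs, path); path }

  ## stage 1: coverage of focal areas vs the random baseline
  coverage <- coverage_vs_random(sim$features, sim$focal, sim$analysis)
  write.csv(coverage$records, put(file.path(outdir, "coverage_records.csv")),
            row.names = FALSE)

  ## stage 2: prioritization scenarios + equal-area comparison
  current <- mask_union(sim$protected, sim$focal, "current_protection")
  scenario_results <- list()
  for (sc in scenarios) {
    cfg <- prioritizer_config(objective = scenario_objective(sc),
                              z_exponent = z_exponent, warp = warp)
    rmask <- build_removal_mask(sc, sim$protected, sim$focal, sim$grid)
    rank <- rank_landscape(sim$stack, cfg, rmask)
    log_lines <- c(log_lines,
                   sprintf("scenario %s: objective=%s z=%g warp=%d tie_break=%s",
                           sc, cfg$objective, cfg$z_exponent, cfg$warp,
                           cfg$tie_break))
    if (write_rank_maps)
      write_raster(rank$rank_map,
                   put(file.path(outdir, paste0("rank_", sc, ".asc"))))
    write.csv(rank$performance,
              put(file.path(outdir, paste0("performance_", sc, ".csv"))),
              row.names = FALSE)
    eq <- if (!grepl("outside_focal", sc))
      equal_area_comparison(sim$features, current, rank$rank_map,
                            sim$analysis)
    else NULL
    if (!is.null(eq))
      write.csv(eq$table,
                put(file.path(outdir, paste0("equal_area_", sc, ".csv"))),
                row.names = FALSE)
    scenario_results[[sc]] <- list(config = cfg, rank = rank,
                                   equal_area = eq)
  }

  ## stage 3: threat exposure (skipped with a warning if layers are absent)
  threat <- NULL
  if (length(sim$threats$future_layers) > 0) {
    threat_masks <- lapply(names(sim$threats$future_layers), function(sid)
      lulc_threat_mask(sim$threats$future_layers[[sid]], LULC_THREAT_CLASSES,
                       sim$analysis, sid))
    threat_masks <- c(threat_masks,
                      list(cheatgrass_risk_mask(sim$threats$rr_layer,
                                                sim$analysis)))
    exposures <- exposure_table(sim$features, threat_masks, sim$focal)
    write.csv(exposures, put(file.path(outdir, "threat_exposure.csv")),
              row.names = FALSE)
    threat <- list(exposures = exposures,
                   summary = scenario_summary(exposures, threat_masks,
                                              sim$focal, sim$analysis))
  } else {
    warning("no threat layers in the simulation; threat stage skipped")
    log_lines <- c(log_lines, "threat stage skipped: no threat layers")
  }

  ## summary JSON mirroring the coverage / equal-area / exposure tables
  summary <- list(
    seed = config$seed,
    realized_focal_fraction = sim$truth$realized_focal_fraction,
    realized_protected_fraction = sim$truth$realized_protected_fraction,
    current_protection_fraction = random_baseline(current, sim$analysis),
    coverage = coverage$summary,
    equal_area = lapply(scenario_results, function(r)
      if (is.null(r$equal_area)) NULL else
        list(fraction = r$equal_area$fraction,
             mean_current = mean(r$equal_area$table$current_coverage),
             mean_prioritized = mean(r$equal_area$table$prioritized_coverage),
             test = unclass(r$equal_area$test))),
    threat = if (is.null(threat)) NULL else
      lapply(threat$summary, function(b)
        list(per_scenario = b$per_scenario,
             mean_landscape_exposure_focal = b$mean_landscape_exposure_focal,
             se_landscape_exposure_focal = b$se_landscape_exposure_focal,
             mean_landscape_exposure_region = b$mean_landscape_exposure_region,
             se_landscape_exposure_region = b$se_landscape_exposure_region,
             feature_test = if (is.null(b$feature_test)) NULL
               else unclass(b$feature_test),
             scenario_test = if (is.null(b$scenario_test)) NULL
               else unclass(b$scenario_test))))
  jsonlite::write_json(summary, put(file.path(outdir, "summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  writeLines(log_lines, put(file.path(outdir, "run_log.txt")))
  files <- data.frame(path = basename(outputs),
                      md5 = unname(tools::md5sum(outputs)),
                      stringsAsFactors = FALSE)
  write.csv(files, file.path(outdir, "output_manifest.csv"),
            row.names = FALSE)
  list(sim = sim, coverage = coverage, scenario_results = scenario_results,
       threat = threat, files = files)
}
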