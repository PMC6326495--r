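#' Threat mask
#'
#' Boolean per-cell threat exposure restricted to analysis (habitat) cells,
#' labelled with a threat type (`"lulc"` land-use change, `"cheatgrass"`
#' invasion risk) and a scenario id.
#'
#' @param threatened Logical (or 0/1) matrix.
#' @param grid A [grid_spec()].
#' @param threat_id Threat type string.
#' @param scenario_id Scenario label (e.g. `"A1B"`, `"A2"`, `"B1"`, `"B2"`,
#'   `"cheatgrass"`).
#' @return An object of class `uml_threat` (also a [region_mask()]).
#' @export
threat_mask <- function(threatened, grid, threat_id, scenario_id) {
  m <- region_mask(threatened, grid, mask_id = paste(threat_id, scenario_id,
                                                     sep = ":"))
  m$threat_id <- threat_id
  m$scenario_id <- scenario_id
  class(m) <- c("uml_threat", class(m))
  m
}

#' Threatened cells under a future land-cover scenario
#'
#' A habitat cell counts as threatened when its projected future land-cover
#' class is one of the conversion classes (cropland, developed, forest
#' encroachment, ...). Baseline habitat membership is already encoded by the
#' analysis mask, so only the future class matters; the baseline layer, when
#' given, is used for a grid-compatibility check.
#'
#' @param future [raw_layer()] of projected land-cover class codes.
#' @param threat_classes Numeric vector of class codes that destroy habitat.
#' @param analysis Analysis [region_mask()].
#' @param scenario_id Scenario label.
#' @param baseline Optional baseline land-cover [raw_layer()].
#' @return A [threat_mask()] with `threat_id = "lulc"`.
#' @export
lulc_threat_mask <- function(future, threat_classes, analysis, scenario_id,
                             baseline = NULL) {
  check_same_grid(future$grid, analysis$grid, "future land cover and analysis mask")
  if (!is.null(baseline))
    check_same_grid(baseline$grid, analysis$grid,
                    "baseline land cover and analysis mask")
  thr <- analysis$member & !is.na(future$values) &
    (future$values %in% threat_classes)
  threat_mask(thr, analysis$grid, "lulc", scenario_id)
}

#' High invasion-risk cells from resistance/resilience classes
#'
#' Habitat cells whose resistance-and-resilience class is "low" are at high
#' risk of annual-grass invasion.
#'
#' @param rr_class [raw_layer()] of class codes.
#' @param analysis Analysis [region_mask()].
#' @param codes Named numeric vector mapping `low`, `moderate`, `high` to
#'   their codes (default `c(low = 1, moderate = 2, high = 3)`).
#' @param scenario_id Scenario label (default `"cheatgrass"`).
#' @return A [threat_mask()] with `threat_id = "cheatgrass"`.
#' @export
cheatgrass_risk_mask <- function(rr_class, analysis,
                                 codes = c(low = 1, moderate = 2, high = 3),
                                 scenario_id = "cheatgrass") {
  check_same_grid(rr_class$grid, analysis$grid, "risk classes and analysis mask")
  v <- rr_class$values
  known <- is.na(v) | (v %in% codes)
  if (!all(known))
    uml_stop(sprintf("unknown resistance/resilience class code(s): %s",
                     paste(unique(v[!known]), collapse = ", ")),
             "invalid_class_error")
  threat_mask(analysis$member & !is.na(v) & v == codes[["low"]],
              analysis$grid, "cheatgrass", scenario_id)
}

#' Threat exposure of one feature
#'
#' `exposure_region` is the proportion of the feature's whole (within-region)
#' distribution on threatened cells. `exposure_focal` is the conditional
#' analogue inside the focal region: threatened within-focal mass divided by
#' total within-focal mass, so the two numbers are directly comparable. A
#' feature with zero mass inside the focal region gets `exposure_focal = NA`
#' (flagged, excluded from paired tests).
#'
#' @param feature A [normalized_feature()].
#' @param threat A [threat_mask()].
#' @param focal Focal [region_mask()].
#' @return One-row data frame: `feature_id`, `species_id`, `threat_id`,
#'   `scenario_id`, `exposure_region`, `exposure_focal`, `focal_defined`.
#' @export
exposure <- function(feature, threat, focal) {
  check_same_grid(feature$grid, threat$grid, "feature and threat mask")
  check_same_grid(feature$grid, focal$grid, "feature and focal mask")
  exposure_region <- sum(feature$q[threat$member])
  focal_mass <- sum(feature$q[focal$member])
  exposure_focal <- if (focal_mass > 0)
    sum(feature$q[threat$member & focal$member]) / focal_mass
  else NA_real_
  data.frame(feature_id = feature$feature_id, species_id = feature$species_id,
             threat_id = threat$threat_id, scenario_id = threat$scenario_id,
             exposure_region = exposure_region,
             exposure_focal = exposure_focal,
             focal_defined = focal_mass > 0,
             stringsAsFactors = FALSE)
}

#' Exposure of every feature under every threat mask
#'
#' @param features List of [normalized_feature()]s.
#' @param threats List of [threat_mask()]s.
#' @param focal Focal [region_mask()].
#' @return Data frame of stacked [exposure()] records.
#' @export
exposure_table <- function(features, threats, focal) {
  rows <- lapply(threats, function(th)
    do.call(rbind, lapply(features, exposure, threat = th, focal = focal)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## landscape-level habitat fraction threatened inside a region
landscape_exposure <- function(threat, region) {
  n <- sum(region$member)
  if (n == 0L) uml_stop("region is empty", "empty_landscape_error")
  sum(threat$member & region$member) / n
}

#' Summarize threat exposure across features and scenarios
#'
#' Produces the exposure comparison between the focal region and the whole
#' study region at two levels. Feature level: each feature's exposures are
#' averaged over the land-use scenarios and the within-focal mean is paired
#' against the whole-region mean across features. Landscape level: the
#' habitat-area fraction threatened inside the focal region is paired
#' against the whole-region fraction across the land-use scenarios (degrees
#' of freedom = scenarios - 1). Invasion risk (`threat_id = "cheatgrass"`)
#' is a single-scenario threat and is summarized separately with its own
#' feature-level test.
#'
#' @param exposures Data frame from [exposure_table()].
#' @param threats The list of [threat_mask()]s used to build it.
#' @param focal Focal [region_mask()].
#' @param analysis Analysis [region_mask()].
#' @return A list with components `lulc` (per-scenario landscape fractions,
#'   cross-scenario means and standard errors, feature-level and
#'   scenario-level paired tests) and, when present, `cheatgrass` (landscape
#'   fractions and the feature-level paired test).
#' @export
scenario_summary <- function(exposures, threats, focal, analysis) {
  split_threats <- split(threats, vapply(threats, function(t) t$threat_id,
                                         character(1)))
  out <- list()

  summarize_block <- function(masks, records) {
    scen <- vapply(masks, function(t) t$scenario_id, character(1))
    land_focal <- vapply(masks, landscape_exposure, numeric(1), region = focal)
    land_region <- vapply(masks, landscape_exposure, numeric(1),
                          region = analysis)
    per_scenario <- data.frame(
      scenario_id = scen,
      landscape_exposure_focal = land_focal,
      landscape_exposure_region = land_region,
      mean_exposure_focal = vapply(scen, function(s)
        mean(records$exposure_focal[records$scenario_id == s], na.rm = TRUE),
        numeric(1)),
      mean_exposure_region = vapply(scen, function(s)
        mean(records$exposure_region[records$scenario_id == s]), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    ## per-feature means over scenarios (complete focal records only)
    ok <- records$focal_defined
    ff <- records[ok, , drop = FALSE]
    mean_focal <- tapply(ff$exposure_focal, ff$feature_id, mean)
    mean_region <- tapply(ff$exposure_region, ff$feature_id, mean)
    feature_means <- data.frame(feature_id = names(mean_focal),
                                exposure_focal = as.vector(mean_focal),
                                exposure_region = as.vector(mean_region),
                                stringsAsFactors = FALSE, row.names = NULL)
    feature_test <- if (nrow(feature_means) >= 2L)
      paired_t(feature_means$exposure_focal, feature_means$exposure_region)
    else NULL
    scenario_test <- if (length(scen) >= 2L)
      tryCatch(paired_t(land_focal, land_region),
               degenerate_test_error = function(e) NULL)
    else NULL
    list(per_scenario = per_scenario,
         mean_landscape_exposure_focal = mean(land_focal),
         se_landscape_exposure_focal = if (length(scen) > 1L)
           sd(land_focal) / sqrt(length(scen)) else 0,
         mean_landscape_exposure_region = mean(land_region),
         se_landscape_exposure_region = if (length(scen) > 1L)
           sd(land_region) / sqrt(length(scen)) else 0,
         feature_means = feature_means,
         feature_test = feature_test,
         scenario_test = scenario_test)
  }

  for (tid in names(split_threats)) {
    masks <- split_threats[[tid]]
    records <- exposures[exposures$threat_id == tid, , drop = FALSE]
    out[[tid]] <- summarize_block(masks, records)
  }
  out
}
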