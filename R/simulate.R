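## Synthetic landscapes with the statistical structure the analysis assumes:
## spatially autocorrelated species distributions with a controllable
## range-size spectrum and a controllable association with one umbrella
## species; focal areas carved from the top of the umbrella's distribution;
## protected areas placed independently; threat layers with a controllable
## spatial bias relative to the focal areas. A stand-in for real GIS inputs,
## not an ecological model.

derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647) * 7919 + stream * 104729) %%
    2147483647L
}

#' Simulation configuration
#'
#' Defaults are fixed at the study conditions the package emulates: focal
#' areas covering 23.3% of habitat, protected areas 15.6% (so that the
#' protected-or-focal union is ~35.3% in expectation when the two are
#' independent), land-use threat touching 11.5% of habitat and invasion risk
#' 23.9%, four land-use scenarios, and a threat bias of -0.4 SD which under
#' the Gaussian threshold construction reproduces a roughly halved threat
#' prevalence inside focal areas (about 5-6% inside versus 11.5% overall).
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param n_species Number of species (25 by default, 30 features with the
#'   seasonal pairs below -- a scaled-down analogue of 81 species / 91
#'   features).
#' @param n_seasonal Number of species represented by separate summer and
#'   winter features (partially offset in space).
#' @param n_abundance Number of species carried as continuous abundance
#'   layers rather than binary presence.
#' @param range_size_range Range of occupied landscape fractions; per-species
#'   targets are drawn log-uniformly between the two values.
#' @param autocorr_length Gaussian smoothing SD, in cells, of species and
#'   umbrella fields.
#' @param threat_autocorr_length Gaussian smoothing SD, in cells, of threat
#'   risk fields (smaller: land conversion is patchier than species ranges).
#' @param umbrella_assoc Optional per-species vector in `[-1, 1]`: field
#'   correlation between the species and the umbrella layer. `NULL` draws
#'   uniformly from `assoc_range`.
#' @param assoc_range Sampling range for `umbrella_assoc` when not given;
#'   the default skews positive (most co-occurring species share the
#'   umbrella's habitat, a few avoid it).
#' @param focal_fraction Habitat fraction covered by focal areas.
#' @param protected_fraction Habitat fraction covered by protected areas.
#' @param threat_fraction Habitat fraction threatened per land-use scenario.
#' @param cheatgrass_fraction Habitat fraction at high invasion risk.
#' @param threat_bias Shift, in risk-field SD units, applied to threat risk
#'   inside focal areas; negative values bias threats away from focal areas.
#' @param n_lulc_scenarios Number of land-use scenarios (default 4).
#' @param nonhabitat_fraction Fraction of cells given excluded land-cover
#'   classes (forest/water/cropland/developed) in the baseline layer.
#' @param seed Master seed; fixes all randomness of the generators.
#' @return An object of class `uml_simcfg`.
#' @export
sim_config <- function(n_rows = 100, n_cols = 100, n_species = 25,
                       n_seasonal = 5, n_abundance = 3,
                       range_size_range = c(0.01, 0.6),
                       autocorr_length = 8, threat_autocorr_length = 4,
                       umbrella_assoc = NULL, assoc_range = c(-0.3, 0.9),
                       focal_fraction = 0.233, protected_fraction = 0.156,
                       threat_fraction = 0.115, cheatgrass_fraction = 0.239,
                       threat_bias = -0.4, n_lulc_scenarios = 4,
                       nonhabitat_fraction = 0.15, seed = 1) {
  if (n_species < 1)
    uml_stop("n_species must be >= 1", "invalid_parameter_error")
  if (n_seasonal + n_abundance > n_species)
    uml_stop("n_seasonal + n_abundance cannot exceed n_species",
             "invalid_parameter_error")
  for (f in c(focal_fraction, protected_fraction, threat_fraction,
              cheatgrass_fraction))
    if (!is.numeric(f) || f <= 0 || f >= 1)
      uml_stop("landscape fractions must lie in (0, 1)",
               "invalid_parameter_error")
  if (nonhabitat_fraction < 0 || nonhabitat_fraction >= 1)
    uml_stop("nonhabitat_fraction must lie in [0, 1)",
             "invalid_parameter_error")
  if (!is.null(umbrella_assoc)) {
    if (length(umbrella_assoc) != n_species ||
        any(abs(umbrella_assoc) > 1))
      uml_stop("umbrella_assoc must be length n_species with values in [-1, 1]",
               "invalid_parameter_error")
  }
  if (any(range_size_range <= 0) || any(range_size_range > 1) ||
      range_size_range[1] > range_size_range[2])
    uml_stop("range_size_range must be increasing within (0, 1]",
             "invalid_parameter_error")
  structure(as.list(environment()), class = "uml_simcfg")
}

## truncated-Gaussian row smoother; rows renormalized so edges keep scale
gaussian_smoother <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  W <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
  W / rowSums(W)
}

smooth_matrix <- function(m, sigma) {
  Wr <- gaussian_smoother(nrow(m), sigma)
  Wc <- gaussian_smoother(ncol(m), sigma)
  Wr %*% m %*% t(Wc)
}

standardize <- function(m) {
  s <- sd(as.vector(m))
  if (s == 0) return(m * 0)
  (m - mean(m)) / s
}

## smoothed, standardized white-noise field (draws from the current RNG)
random_field <- function(n_rows, n_cols, sigma) {
  standardize(smooth_matrix(matrix(rnorm(n_rows * n_cols), n_rows, n_cols),
                            sigma))
}

## top-k cells of a field, ties broken by a seeded random permutation;
## candidates restricted to `member` (logical row-major vector) when given
top_fraction_mask <- function(field_mat, fraction, grid, member = NULL,
                              mask_id = "mask") {
  v <- rm_vec(field_mat)
  n_all <- length(v)
  if (is.null(member)) member <- rep(TRUE, n_all)
  cand <- which(member)
  k <- max(1L, round(fraction * length(cand)))
  ord <- cand[order(-v[cand], sample.int(n_all)[cand])]
  sel <- rep(FALSE, n_all)
  sel[ord[seq_len(k)]] <- TRUE
  region_mask(rm_mat(sel, grid), grid, mask_id)
}

sim_grid <- function(config) {
  grid_spec(config$n_rows, config$n_cols, cell_size = 270,
            origin = c(0, config$n_rows * 270),
            crs_tag = "synthetic-equal-area")
}

#' Generate the umbrella species' distribution field
#'
#' A smoothed, standardized Gaussian random field; the umbrella layer the
#' focal areas are carved from and species layers are blended with.
#'
#' @param config A [sim_config()].
#' @return A [raw_layer()] (`layer_id = "umbrella"`).
#' @export
gen_umbrella <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  raw_layer(random_field(config$n_rows, config$n_cols,
                         config$autocorr_length),
            sim_grid(config), "umbrella")
}

#' Generate species distribution layers
#'
#' Each species' latent field is a blend of the umbrella field and an
#' independent smoothed-noise field, weighted by the species' umbrella
#' association `a` (`a * U + sqrt(1 - a^2) * E`), then thresholded at the
#' species' drawn range-size quantile to binary presence. Abundance-type
#' species keep the continuous positive part above the threshold. Seasonal
#' species get a second, partially offset winter layer.
#'
#' @param config A [sim_config()].
#' @param umbrella Optional precomputed [gen_umbrella()] layer.
#' @return A list: `layers` (named list of [raw_layer()]s), `manifest`
#'   (data frame `feature_id`, `species_id`, `season_tag`), `truth`
#'   (data frame of per-species association, range-size target and type).
#' @export
gen_species <- function(config, umbrella = NULL) {
  if (is.null(umbrella)) umbrella <- gen_umbrella(config)
  U <- umbrella$values
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_species
  assoc <- config$umbrella_assoc
  if (is.null(assoc))
    assoc <- runif(n, config$assoc_range[1], config$assoc_range[2])
  lr <- log(config$range_size_range)
  target_frac <- exp(runif(n, lr[1], lr[2]))
  n_cells <- config$n_rows * config$n_cols
  offset <- max(1L, round(2 * config$autocorr_length))

  threshold_layer <- function(field, frac, id, continuous) {
    k <- max(1L, round(frac * n_cells))
    v <- rm_vec(field)
    thr <- sort(v, decreasing = TRUE)[k]
    pres <- v >= thr
    ## exact-count occupancy even under (improbable) ties
    if (sum(pres) > k) pres <- rank(-v, ties.method = "first") <= k
    vals <- if (continuous) ifelse(pres, v - thr + 1e-6, 0) else pres + 0
    raw_layer(rm_mat(vals, sim_grid(config)), sim_grid(config), id)
  }

  layers <- list(); manifest <- NULL
  types <- character(n)
  for (s in seq_len(n)) {
    a <- assoc[s]
    E <- random_field(config$n_rows, config$n_cols, config$autocorr_length)
    field <- a * U + sqrt(1 - a^2) * E
    sp_id <- sprintf("sp%02d", s)
    seasonal <- s <= config$n_seasonal
    continuous <- !seasonal &&
      s <= config$n_seasonal + config$n_abundance
    types[s] <- if (seasonal) "seasonal" else if (continuous) "abundance"
      else "binary"
    if (seasonal) {
      winter_field <- field[c((offset + 1):nrow(field), 1:offset),
                            c((offset + 1):ncol(field), 1:offset)]
      for (season in c("summer", "winter")) {
        fid <- paste0(sp_id, "_", season)
        fld <- if (season == "summer") field else winter_field
        layers[[fid]] <- threshold_layer(fld, target_frac[s], fid, FALSE)
        manifest <- rbind(manifest,
                          data.frame(feature_id = fid, species_id = sp_id,
                                     season_tag = season,
                                     stringsAsFactors = FALSE))
      }
    } else {
      layers[[sp_id]] <- threshold_layer(field, target_frac[s], sp_id,
                                         continuous)
      manifest <- rbind(manifest,
                        data.frame(feature_id = sp_id, species_id = sp_id,
                                   season_tag = "year_round",
                                   stringsAsFactors = FALSE))
    }
  }
  truth <- data.frame(species_id = sprintf("sp%02d", seq_len(n)),
                      umbrella_assoc = assoc,
                      target_range_fraction = target_frac,
                      type = types, stringsAsFactors = FALSE)
  list(layers = layers, manifest = manifest, truth = truth)
}

#' Derive focal areas from the umbrella distribution
#'
#' The focal mask is the top quantile of the (further smoothed) umbrella
#' layer over analysis cells, hitting the target landscape fraction exactly
#' (up to one cell); smoothing before thresholding biases the mask towards
#' contiguous patches. Ties -- e.g. a completely uniform umbrella layer --
#' are broken by a seeded random permutation.
#'
#' @param umbrella [raw_layer()] of the umbrella distribution.
#' @param focal_fraction Target fraction of analysis cells, in `(0, 1)`.
#' @param seed Integer seed (tie-breaking only).
#' @param analysis Optional analysis [region_mask()]; default all cells.
#' @param smooth_sigma Extra smoothing SD in cells before thresholding.
#' @return A [region_mask()] (`mask_id = "focal"`).
#' @export
gen_focal_areas <- function(umbrella, focal_fraction, seed = 1,
                            analysis = NULL, smooth_sigma = 2) {
  if (!is.numeric(focal_fraction) || focal_fraction <= 0 ||
      focal_fraction >= 1)
    uml_stop("focal_fraction must lie in (0, 1)", "invalid_parameter_error")
  set.seed(derive_seed(seed, 3L))
  member <- if (is.null(analysis)) NULL else rm_vec(analysis$member)
  sm <- smooth_matrix(umbrella$values, smooth_sigma)
  top_fraction_mask(sm, focal_fraction, umbrella$grid, member, "focal")
}

#' Generate protected areas
#'
#' A top-quantile mask of an independent smoothed random field: contiguous
#' protected patches placed without regard to the umbrella layer. Overlap
#' with focal areas is allowed (as it is between real protected areas and
#' focal areas).
#'
#' @param grid A [grid_spec()].
#' @param protected_fraction Target fraction of analysis cells, in `(0, 1)`.
#' @param seed Integer seed.
#' @param analysis Optional analysis [region_mask()]; default all cells.
#' @param sigma Smoothing SD in cells (default 4).
#' @return A [region_mask()] (`mask_id = "protected"`).
#' @export
gen_protected_areas <- function(grid, protected_fraction, seed = 1,
                                analysis = NULL, sigma = 4) {
  if (!is.numeric(protected_fraction) || protected_fraction <= 0 ||
      protected_fraction >= 1)
    uml_stop("protected_fraction must lie in (0, 1)",
             "invalid_parameter_error")
  set.seed(derive_seed(seed, 4L))
  field <- random_field(grid$n_rows, grid$n_cols, sigma)
  member <- if (is.null(analysis)) NULL else rm_vec(analysis$member)
  top_fraction_mask(field, protected_fraction, grid, member, "protected")
}

#' Generate threat layers
#'
#' Per land-use scenario, a smoothed standardized risk field is shifted by
#' `threat_bias` (in SD units) inside the focal region and thresholded to
#' the target threatened fraction of analysis cells; threatened cells are
#' written into a projected land-cover layer as cropland conversion (class
#' 82). A single invasion-risk scenario is generated the same way at its own
#' fraction and expressed as resistance/resilience classes (1 = low = high
#' risk, 2 = moderate, 3 = high).
#'
#' @param config A [sim_config()].
#' @param focal Focal [region_mask()].
#' @param analysis Analysis [region_mask()].
#' @param seed Integer seed (defaults to the config's).
#' @return A list: `masks` (list of [threat_mask()]s: the land-use scenarios
#'   then cheatgrass), `future_layers` (projected land-cover [raw_layer()]s),
#'   `rr_layer` (resistance/resilience class [raw_layer()]), `truth`
#'   (per-scenario bias).
#' @export
gen_threats <- function(config, focal, analysis, seed = config$seed) {
  set.seed(derive_seed(seed, 6L))
  grid <- focal$grid
  scen_ids <- c("A1B", "A2", "B1", "B2",
                sprintf("scen%d", seq_len(max(0, config$n_lulc_scenarios - 4))))
  scen_ids <- scen_ids[seq_len(config$n_lulc_scenarios)]
  member <- rm_vec(analysis$member)
  focal_shift <- config$threat_bias * (focal$member + 0)

  masks <- list(); future_layers <- list()
  for (sid in scen_ids) {
    risk <- random_field(config$n_rows, config$n_cols,
                         config$threat_autocorr_length) + focal_shift
    thr_mask <- top_fraction_mask(risk, config$threat_fraction, grid,
                                  member, paste0("threat_", sid))
    masks[[sid]] <- threat_mask(thr_mask$member, grid, "lulc", sid)
    future <- matrix(NA_real_, grid$n_rows, grid$n_cols)
    future[analysis$member] <- 52            # shrubland persists
    future[thr_mask$member] <- 82            # converted to cropland
    future_layers[[sid]] <- raw_layer(future, grid, paste0("lulc2050_", sid))
  }

  risk <- random_field(config$n_rows, config$n_cols,
                       config$threat_autocorr_length) + focal_shift
  cheat <- top_fraction_mask(risk, config$cheatgrass_fraction, grid, member,
                             "cheatgrass")
  masks[["cheatgrass"]] <- threat_mask(cheat$member, grid, "cheatgrass",
                                       "cheatgrass")
  rr <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  rr[analysis$member] <- ifelse(risk[analysis$member] > median(risk), 2, 3)
  rr[cheat$member] <- 1
  rr_layer <- raw_layer(rr, grid, "resistance_resilience")

  truth <- data.frame(scenario_id = c(scen_ids, "cheatgrass"),
                      threat_bias = config$threat_bias,
                      target_fraction = c(rep(config$threat_fraction,
                                              length(scen_ids)),
                                          config$cheatgrass_fraction),
                      stringsAsFactors = FALSE)
  list(masks = masks, future_layers = future_layers, rr_layer = rr_layer,
       truth = truth)
}

#' Simulate a complete synthetic landscape
#'
#' Runs every generator under one master seed and assembles the analysis
#' inputs: baseline land cover (with excluded classes), the analysis mask,
#' umbrella layer, species layers and manifest, focal and protected masks,
#' threat layers, the normalized feature set and the [landscape_stack()],
#' plus the truth record written at generation time.
#'
#' @param config A [sim_config()].
#' @return A list with components `config`, `grid`, `baseline_landcover`,
#'   `analysis`, `umbrella`, `species`, `focal`, `protected`, `threats`,
#'   `features`, `stack`, `truth`.
#' @export
simulate_landscape <- function(config) {
  grid <- sim_grid(config)

  ## baseline land cover: contiguous non-habitat (forest/water/crop/urban)
  ## patches over a shrub/grass matrix, then the exclusion rule
  set.seed(derive_seed(config$seed, 5L))
  lc_field <- random_field(config$n_rows, config$n_cols,
                           config$autocorr_length)
  v <- rm_vec(lc_field)
  n_cells <- length(v)
  n_non <- round(config$nonhabitat_fraction * n_cells)
  lc <- rep(52, n_cells)                       # shrubland
  lc[sample.int(n_cells, round(0.3 * n_cells))] <- 71   # grassland pockets
  if (n_non > 0) {
    ord <- order(-v)
    non <- ord[seq_len(n_non)]
    classes <- c(41, 11, 82, 21)               # forest, water, crop, developed
    lc[non] <- classes[1 + (seq_along(non) %% length(classes))]
  }
  baseline <- raw_layer(rm_mat(lc, grid), grid, "landcover_baseline")
  analysis <- apply_exclusions(baseline,
                               excluded_classes = c(11, 21, 22, 23, 24,
                                                    41, 42, 43, 81, 82))

  umbrella <- gen_umbrella(config)
  species <- gen_species(config, umbrella)
  focal <- gen_focal_areas(umbrella, config$focal_fraction, config$seed,
                           analysis)
  protected <- gen_protected_areas(grid, config$protected_fraction,
                                   config$seed, analysis)
  threats <- gen_threats(config, focal, analysis)

  features <- list(); kept <- logical(nrow(species$manifest))
  for (i in seq_len(nrow(species$manifest))) {
    fid <- species$manifest$feature_id[i]
    f <- tryCatch(
      normalize_feature(species$layers[[fid]], analysis,
                        species_id = species$manifest$species_id[i],
                        season_tag = species$manifest$season_tag[i]),
      empty_feature_error = function(e) NULL)
    kept[i] <- !is.null(f)
    if (kept[i]) features[[length(features) + 1L]] <- f
  }
  if (!all(kept))
    message(sprintf("dropped %d feature(s) with no mass on the analysis mask: %s",
                    sum(!kept),
                    paste(species$manifest$feature_id[!kept], collapse = ", ")))

  stack <- landscape_stack(features, analysis, focal_mask = focal,
                           protected_mask = protected)
  truth <- list(species = species$truth, threats = threats$truth,
                realized_focal_fraction = random_baseline(focal, analysis),
                realized_protected_fraction = random_baseline(protected,
                                                              analysis))
  list(config = config, grid = grid, baseline_landcover = baseline,
       analysis = analysis, umbrella = umbrella, species = species,
       focal = focal, protected = protected, threats = threats,
       features = features, stack = stack, truth = truth)
}

#' Write a simulated landscape to a directory
#'
#' Writes every layer and mask as an ASCII grid, the feature manifest as
#' CSV, and the truth record as JSON -- the complete input set the analysis
#' stages read back.
#'
#' @param sim Output of [simulate_landscape()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(sim$baseline_landcover, file.path(dir, "landcover_baseline.asc"))
  write_raster(sim$analysis, file.path(dir, "analysis_mask.asc"))
  write_raster(sim$umbrella, file.path(dir, "umbrella.asc"))
  write_raster(sim$focal, file.path(dir, "focal_mask.asc"))
  write_raster(sim$protected, file.path(dir, "protected_mask.asc"))
  for (fid in names(sim$species$layers))
    write_raster(sim$species$layers[[fid]], file.path(dir, paste0(fid, ".asc")))
  for (sid in names(sim$threats$future_layers))
    write_raster(sim$threats$future_layers[[sid]],
                 file.path(dir, paste0("lulc2050_", sid, ".asc")))
  write_raster(sim$threats$rr_layer,
               file.path(dir, "resistance_resilience.asc"))
  manifest <- sim$species$manifest
  manifest$path <- paste0(manifest$feature_id, ".asc")
  write.csv(manifest, file.path(dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
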