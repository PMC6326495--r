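#' Block-aggregate a layer taking the block maximum
#'
#' Coarsens a layer by an integer factor, each output cell taking the maximum
#' over the non-nodata input cells of its block (the rule used to bring fine
#' species distribution models onto the working resolution, e.g. 90 m to
#' 270 m with `factor = 3`). Partial blocks at the right/bottom edge are
#' allowed; all-nodata blocks stay nodata.
#'
#' @param layer A [raw_layer()].
#' @param factor Positive integer aggregation factor.
#' @return A [raw_layer()] on the coarsened grid (`cell_size` multiplied by
#'   `factor`, same origin and crs).
#' @export
aggregate_max <- function(layer, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    uml_stop("aggregation factor must be a positive integer",
             "invalid_parameter_error")
  if (factor == 1L) return(layer)
  g <- layer$grid
  out_r <- ceiling(g$n_rows / factor)
  out_c <- ceiling(g$n_cols / factor)
  out <- matrix(NA_real_, out_r, out_c)
  for (br in seq_len(out_r)) {
    rows <- ((br - 1L) * factor + 1L):min(br * factor, g$n_rows)
    for (bc in seq_len(out_c)) {
      cols <- ((bc - 1L) * factor + 1L):min(bc * factor, g$n_cols)
      block <- layer$values[rows, cols]
      if (!all(is.na(block))) out[br, bc] <- max(block, na.rm = TRUE)
    }
  }
  out_grid <- grid_spec(out_r, out_c, cell_size = g$cell_size * factor,
                        origin = g$origin, crs_tag = g$crs_tag,
                        nodata = g$nodata)
  raw_layer(out, out_grid, layer$layer_id)
}

#' Build the analysis mask by excluding land-cover classes
#'
#' Marks as habitat every non-nodata cell whose land-cover class is not in
#' `excluded_classes` (e.g. dropping forest, water, cropland and developed
#' land to leave shrubland/grassland). Aggregation to the working resolution
#' is done first, exclusion second: the mask lives on the aggregated grid so
#' that all layers share one grid.
#'
#' @param landcover A [raw_layer()] of integer class codes on the analysis
#'   grid.
#' @param excluded_classes Numeric vector of class codes to exclude.
#' @param mask_id Identifier for the returned mask.
#' @return A [region_mask()] (the analysis mask).
#' @export
apply_exclusions <- function(landcover, excluded_classes,
                             mask_id = "analysis") {
  member <- !is.na(landcover$values) &
    !(landcover$values %in% excluded_classes)
  region_mask(member, landcover$grid, mask_id)
}

#' Normalize a distribution layer to proportions
#'
#' Converts a non-negative distribution or abundance layer into per-cell
#' proportions of the feature's total within-region distribution: each
#' analysis cell gets `value / sum(values over analysis cells)`; nodata and
#' out-of-mask cells become 0. Binary presence layers therefore normalize to
#' uniform weight over occupied cells; abundance layers keep their relative
#' weighting.
#'
#' @param layer A [raw_layer()] with non-negative values.
#' @param analysis_mask A [region_mask()] on the same grid.
#' @param species_id,season_tag Passed to [normalized_feature()].
#' @return A [normalized_feature()].
#' @export
normalize_feature <- function(layer, analysis_mask,
                              species_id = layer$layer_id,
                              season_tag = "year_round") {
  check_same_grid(layer$grid, analysis_mask$grid, "layer and analysis mask")
  v <- layer$values
  if (any(v < 0, na.rm = TRUE))
    uml_stop(sprintf("layer '%s' has negative values", layer$layer_id),
             "invalid_parameter_error")
  v[is.na(v)] <- 0
  v[!analysis_mask$member] <- 0
  total <- sum(v)
  if (total <= 0)
    uml_stop(sprintf("feature '%s' has no mass on the analysis mask; drop it",
                     layer$layer_id), "empty_feature_error")
  q <- v / total
  ## guard against accumulation error on very large grids
  q <- q / sum(q)
  normalized_feature(q, layer$grid, feature_id = layer$layer_id,
                     species_id = species_id, season_tag = season_tag)
}

#' Feature inclusion rule
#'
#' Decides whether a species distribution qualifies for the analysis. A
#' feature is kept when its range covers at least `t1` of the study region
#' (inclusive), or when strictly more than `t2` of its entire distribution
#' falls inside the region. The first criterion admits widespread species,
#' the second small-ranged species concentrated in the region.
#'
#' @param range_fraction_of_region Proportion of the study region overlapped
#'   by the species range, in `[0, 1]`.
#' @param fraction_of_range_in_region Proportion of the species' entire
#'   distribution inside the region, in `[0, 1]`.
#' @param t1,t2 Thresholds (defaults 0.20 and 0.20).
#' @return Logical: keep (`TRUE`) or drop (`FALSE`).
#' @export
select_features <- function(range_fraction_of_region,
                            fraction_of_range_in_region,
                            t1 = 0.20, t2 = 0.20) {
  a <- range_fraction_of_region
  b <- fraction_of_range_in_region
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      is.na(a) || is.na(b) || a < 0 || a > 1 || b < 0 || b > 1)
    uml_stop("both arguments must be proportions in [0, 1]",
             "invalid_parameter_error")
  (a >= t1) || (b > t2)
}
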