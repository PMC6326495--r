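#' @useDynLib umbrellar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd quantile median
#' @importFrom utils read.csv write.csv
NULL

## Internal error helper: every package error carries a specific condition
## class plus "umbrellar_error", so callers can test for the failure mode.
uml_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "umbrellar_error")))
}

#' Grid specification
#'
#' A lightweight description of a regular, north-up raster grid. All layers,
#' masks and rank maps taking part in one analysis must share an identical
#' grid: same dimensions, cell size and top-left origin.
#'
#' @param n_rows,n_cols Positive integers, grid dimensions.
#' @param cell_size Edge length of one (square) cell, in map units.
#' @param origin Numeric length-2, map coordinates of the top-left corner
#'   `(x, y)`. Rows run downward from `origin[2]`.
#' @param crs_tag Opaque coordinate-reference identifier string; compared
#'   verbatim, never interpreted.
#' @param nodata Sentinel value used when layers are written to disk.
#'   Internally missing cells are held as `NA`.
#' @return An object of class `uml_grid`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1,
                      origin = c(0, n_rows * cell_size),
                      crs_tag = "", nodata = -9999) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    uml_stop("grid dimensions must be positive integers", "invalid_parameter_error")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    uml_stop("cell_size must be a positive number", "invalid_parameter_error")
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 origin = as.numeric(origin), crs_tag = crs_tag,
                 nodata = nodata),
            class = "uml_grid")
}

#' @export
print.uml_grid <- function(x, ...) {
  cat(sprintf("<grid %d x %d, cell %g, origin (%g, %g)%s>\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2],
              if (nzchar(x$crs_tag)) paste0(", crs ", x$crs_tag) else ""))
  invisible(x)
}

#' Compare two grids for compatibility
#'
#' @param a,b `uml_grid` objects.
#' @param tol Numeric tolerance on cell size and origin.
#' @return `TRUE` if the grids describe the same cell lattice.
#' @export
grids_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol) &&
    identical(a$crs_tag, b$crs_tag)
}

check_same_grid <- function(a, b, what = "layers") {
  if (!grids_equal(a, b))
    uml_stop(paste(what, "are not on the same grid"), "grid_mismatch_error")
  invisible(TRUE)
}

## Row-major (0-based linear index = row * n_cols + col) flattening helpers.
## All removal-order bookkeeping and tie-breaking is defined on this ordering.
rm_vec <- function(m) as.vector(t(m))
rm_mat <- function(v, grid) matrix(v, nrow = grid$n_rows, byrow = TRUE)

#' Raw raster layer
#'
#' Holds per-cell real values on a grid. Missing (nodata) cells are `NA`
#' internally; the grid's `nodata` sentinel only appears in files.
#'
#' @param values Numeric matrix `n_rows x n_cols` (`NA` = nodata).
#' @param grid A [grid_spec()].
#' @param layer_id Identifier string.
#' @return An object of class `uml_layer`.
#' @export
raw_layer <- function(values, grid, layer_id = "layer") {
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    uml_stop("values matrix does not match grid dimensions", "grid_mismatch_error")
  if (any(is.infinite(values)))
    uml_stop("layer values must be finite or NA", "invalid_parameter_error")
  structure(list(grid = grid, values = values, layer_id = layer_id),
            class = "uml_layer")
}

#' @export
print.uml_layer <- function(x, ...) {
  cat(sprintf("<layer '%s' %d x %d, %d nodata cells>\n", x$layer_id,
              x$grid$n_rows, x$grid$n_cols, sum(is.na(x$values))))
  invisible(x)
}

#' Region mask
#'
#' Boolean cell membership (analysis region, focal areas, protected areas).
#' `NA` in the input is treated as non-member.
#'
#' @param member Logical (or 0/1) matrix.
#' @param grid A [grid_spec()].
#' @param mask_id Identifier string.
#' @return An object of class `uml_mask`.
#' @export
region_mask <- function(member, grid, mask_id = "mask") {
  member <- as.matrix(member)
  if (nrow(member) != grid$n_rows || ncol(member) != grid$n_cols)
    uml_stop("mask matrix does not match grid dimensions", "grid_mismatch_error")
  member <- !is.na(member) & (member != 0)
  structure(list(grid = grid, member = member, mask_id = mask_id),
            class = "uml_mask")
}

#' @export
print.uml_mask <- function(x, ...) {
  cat(sprintf("<mask '%s' %d x %d, %d member cells (%.1f%%)>\n", x$mask_id,
              x$grid$n_rows, x$grid$n_cols, sum(x$member),
              100 * mean(x$member)))
  invisible(x)
}

#' Number of member cells in a mask
#' @param mask A [region_mask()].
#' @return Integer count.
#' @export
mask_size <- function(mask) sum(mask$member)

#' Normalized conservation feature
#'
#' One feature's distribution expressed as per-cell proportions of its
#' original full distribution: values are non-negative, zero outside the
#' analysis mask, and sum to 1 over analysis cells. Constructed by
#' [normalize_feature()].
#'
#' @param q Numeric matrix of proportions.
#' @param grid A [grid_spec()].
#' @param feature_id Feature identifier (one seasonal distribution = one
#'   feature).
#' @param species_id Species the feature belongs to (defaults to
#'   `feature_id`); used when coverage tallies are aggregated per species.
#' @param season_tag One of `"year_round"`, `"summer"`, `"winter"`.
#' @return An object of class `uml_feature`.
#' @export
normalized_feature <- function(q, grid, feature_id, species_id = feature_id,
                               season_tag = "year_round") {
  q <- as.matrix(q)
  if (nrow(q) != grid$n_rows || ncol(q) != grid$n_cols)
    uml_stop("q matrix does not match grid dimensions", "grid_mismatch_error")
  if (!season_tag %in% c("year_round", "summer", "winter"))
    uml_stop("season_tag must be year_round, summer or winter",
             "invalid_parameter_error")
  if (any(is.na(q)) || any(q < 0))
    uml_stop("q must be non-negative and NA-free", "invalid_parameter_error")
  s <- sum(q)
  if (abs(s - 1) > 1e-9)
    uml_stop(sprintf("feature '%s' proportions sum to %.12f, not 1",
                     feature_id, s), "invalid_parameter_error")
  structure(list(grid = grid, q = q, feature_id = feature_id,
                 species_id = species_id, season_tag = season_tag),
            class = "uml_feature")
}

#' @export
print.uml_feature <- function(x, ...) {
  cat(sprintf("<feature '%s' (%s, %s), %d occupied cells>\n", x$feature_id,
              x$species_id, x$season_tag, sum(x$q > 0)))
  invisible(x)
}

#' Landscape stack
#'
#' Bundles the aligned inputs of one analysis: normalized features, the
#' analysis mask (habitat cells), an optional per-cell cost layer (default 1
#' everywhere: ranking on biological criteria alone), and optional focal and
#' protected masks.
#'
#' @param features List of [normalized_feature()] objects.
#' @param analysis_mask A [region_mask()] of habitat cells.
#' @param cost Optional numeric matrix of positive per-cell costs.
#' @param focal_mask,protected_mask Optional [region_mask()]s; must be
#'   subsets of the analysis mask.
#' @return An object of class `uml_stack`.
#' @export
landscape_stack <- function(features, analysis_mask, cost = NULL,
                            focal_mask = NULL, protected_mask = NULL) {
  if (length(features) < 1L)
    uml_stop("a landscape stack needs at least one feature",
             "invalid_parameter_error")
  grid <- analysis_mask$grid
  if (mask_size(analysis_mask) == 0L)
    uml_stop("analysis mask is empty", "empty_landscape_error")
  for (f in features) {
    check_same_grid(f$grid, grid, sprintf("feature '%s' and analysis mask", f$feature_id))
    if (any(f$q[!analysis_mask$member] != 0))
      uml_stop(sprintf("feature '%s' has mass outside the analysis mask",
                       f$feature_id), "invalid_parameter_error")
  }
  if (is.null(cost)) {
    cost <- matrix(1, grid$n_rows, grid$n_cols)
  } else {
    cost <- as.matrix(cost)
    if (nrow(cost) != grid$n_rows || ncol(cost) != grid$n_cols)
      uml_stop("cost matrix does not match grid dimensions", "grid_mismatch_error")
    if (any(!is.finite(cost[analysis_mask$member])) ||
        any(cost[analysis_mask$member] <= 0))
      uml_stop("cost must be positive and finite on analysis cells",
               "invalid_parameter_error")
  }
  for (m in list(focal_mask, protected_mask)) {
    if (!is.null(m)) {
      check_same_grid(m$grid, grid, "mask and analysis mask")
      if (any(m$member & !analysis_mask$member))
        uml_stop(sprintf("mask '%s' is not a subset of the analysis mask",
                         m$mask_id), "invalid_parameter_error")
    }
  }
  ids <- vapply(features, function(f) f$feature_id, character(1))
  if (anyDuplicated(ids))
    uml_stop("duplicate feature_ids in stack", "invalid_parameter_error")
  structure(list(grid = grid, features = features,
                 analysis_mask = analysis_mask, cost = cost,
                 focal_mask = focal_mask, protected_mask = protected_mask),
            class = "uml_stack")
}

#' @export
print.uml_stack <- function(x, ...) {
  cat(sprintf("<landscape stack: %d features, %d analysis cells (%d x %d grid)>\n",
              length(x$features), mask_size(x$analysis_mask),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Feature identifiers of a stack
#' @param stack A [landscape_stack()].
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(stack) {
  vapply(stack$features, function(f) f$feature_id, character(1))
}
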