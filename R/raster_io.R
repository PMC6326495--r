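## Layer and mask I/O in the ESRI ASCII grid (.asc) format: a plain-text,
## widely interoperable single-band raster with grid geometry in the header.
## Values are written with full double precision (%.17g) so that
## read(write(x)) reproduces values, grid and nodata exactly.

#' Read a raster layer from an ESRI ASCII grid file
#'
#' @param path Path to a `.asc` file.
#' @param layer_id Identifier for the returned layer (defaults to the file
#'   name without extension).
#' @param crs_tag Optional CRS identifier to attach to the grid (the `.asc`
#'   header does not carry one).
#' @return A [raw_layer()].
#' @export
read_raster <- function(path, layer_id = NULL, crs_tag = "") {
  if (!file.exists(path))
    uml_stop(sprintf("cannot read raster '%s': no such file", path), "io_error")
  lines <- readLines(path, n = 6L)
  header <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))))
      uml_stop(sprintf("'%s' is not a single-band ASCII grid (bad header line '%s')",
                       path, ln), "unsupported_format_error")
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  req <- c("ncols", "nrows", "cellsize", "nodata_value")
  if (!all(req %in% names(header)) ||
      !(("xllcorner" %in% names(header) && "yllcorner" %in% names(header)) ||
        ("xllcenter" %in% names(header) && "yllcenter" %in% names(header))))
    uml_stop(sprintf("'%s' is missing required ASCII grid header fields", path),
             "unsupported_format_error")
  n_cols <- as.integer(header$ncols); n_rows <- as.integer(header$nrows)
  cell <- header$cellsize
  if (!is.null(header$xllcorner)) {
    xll <- header$xllcorner; yll <- header$yllcorner
  } else {
    xll <- header$xllcenter - cell / 2; yll <- header$yllcenter - cell / 2
  }
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(vals) != n_rows * n_cols)
    uml_stop(sprintf("'%s' holds %d values, expected %d (multi-band or truncated files are unsupported)",
                     path, length(vals), n_rows * n_cols),
             "unsupported_format_error")
  nodata <- header$nodata_value
  vals[vals == nodata] <- NA_real_
  grid <- grid_spec(n_rows, n_cols, cell_size = cell,
                    origin = c(xll, yll + n_rows * cell),
                    crs_tag = crs_tag, nodata = nodata)
  if (is.null(layer_id)) layer_id <- sub("\\.[^.]*$", "", basename(path))
  raw_layer(rm_mat(vals, grid), grid, layer_id)
}

#' Write a layer, mask, removal mask or rank map to an ESRI ASCII grid file
#'
#' Masks are encoded 0/1, removal masks as integer levels, layers and rank
#' maps at full double precision; nodata cells are written as the grid's
#' nodata sentinel (masks use 255 by convention).
#'
#' @param x A [raw_layer()], [region_mask()], [removal_mask()] or rank map.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  g <- x$grid
  if (inherits(x, "uml_layer")) {
    vals <- x$values; nodata <- g$nodata
  } else if (inherits(x, "uml_mask")) {
    vals <- x$member + 0; nodata <- 255
  } else if (inherits(x, "uml_removal")) {
    vals <- x$level; nodata <- 255
  } else if (inherits(x, "uml_rankmap")) {
    vals <- x$rank_fraction; nodata <- g$nodata
  } else {
    uml_stop("write_raster: unsupported object type", "invalid_parameter_error")
  }
  v <- rm_vec(vals)
  v_chr <- sprintf("%.17g", v)
  v_chr[is.na(v)] <- sprintf("%.17g", as.numeric(nodata))
  header <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$origin[1]),
    sprintf("yllcorner %.17g", g$origin[2] - g$n_rows * g$cell_size),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %.17g", as.numeric(nodata)))
  rows <- vapply(seq_len(g$n_rows), function(r) {
    paste(v_chr[((r - 1L) * g$n_cols + 1L):(r * g$n_cols)], collapse = " ")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a region mask from an ASCII grid file
#'
#' Cells equal to 1 become members; 0 and nodata (255) become non-members.
#'
#' @param path Path to a 0/1-coded `.asc` file.
#' @param mask_id Identifier for the mask.
#' @return A [region_mask()].
#' @export
read_mask <- function(path, mask_id = NULL) {
  if (is.null(mask_id)) mask_id <- sub("\\.[^.]*$", "", basename(path))
  layer <- read_raster(path, layer_id = mask_id)
  region_mask(!is.na(layer$values) & layer$values == 1, layer$grid, mask_id)
}

#' Read a rank map from an ASCII grid file
#'
#' Inverse of [write_raster()] for rank maps: nodata cells are non-analysis
#' cells, every other cell holds its removal-rank fraction in `(0, 1]`.
#'
#' @param path Path to a rank-map `.asc` file.
#' @return An object of class `uml_rankmap`.
#' @export
read_rank_map <- function(path) {
  layer <- read_raster(path)
  v <- layer$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    uml_stop(sprintf("'%s' does not hold rank fractions in (0, 1]", path),
             "unsupported_format_error")
  structure(list(grid = layer$grid, rank_fraction = v,
                 n_analysis = sum(!is.na(v))),
            class = "uml_rankmap")
}

#' Read a feature manifest
#'
#' The manifest is a CSV with columns `feature_id`, `species_id`,
#' `season_tag`, `path` (paths relative to the manifest's directory unless
#' absolute) listing one distribution layer per conservation feature.
#'
#' @param path Path to the manifest CSV.
#' @return A data frame with the four columns, `path` resolved.
#' @export
read_feature_manifest <- function(path) {
  if (!file.exists(path))
    uml_stop(sprintf("manifest '%s' not found", path), "io_error")
  m <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("feature_id", "species_id", "season_tag", "path")
  if (!all(req %in% names(m)))
    uml_stop("manifest must have columns feature_id, species_id, season_tag, path",
             "unsupported_format_error")
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Load a landscape stack from a manifest and mask files
#'
#' Reads every feature layer listed in the manifest, normalizes each over
#' the analysis mask, and assembles a [landscape_stack()]. Features with no
#' mass on the analysis mask are an error unless `drop_empty = TRUE`.
#'
#' @param manifest_path Path to the feature manifest CSV.
#' @param analysis_mask_path Path to the 0/1 analysis-mask `.asc`.
#' @param focal_mask_path,protected_mask_path Optional mask paths.
#' @param drop_empty Drop features with no in-mask mass instead of erroring.
#' @return A [landscape_stack()].
#' @export
read_stack <- function(manifest_path, analysis_mask_path,
                       focal_mask_path = NULL, protected_mask_path = NULL,
                       drop_empty = FALSE) {
  manifest <- read_feature_manifest(manifest_path)
  analysis <- read_mask(analysis_mask_path, "analysis")
  features <- list()
  for (i in seq_len(nrow(manifest))) {
    layer <- read_raster(manifest$path[i], layer_id = manifest$feature_id[i])
    f <- tryCatch(
      normalize_feature(layer, analysis,
                        species_id = manifest$species_id[i],
                        season_tag = manifest$season_tag[i]),
      umbrellar_error = function(e) {
        if (drop_empty && inherits(e, "empty_feature_error")) NULL else stop(e)
      })
    if (!is.null(f)) features[[length(features) + 1L]] <- f
  }
  focal <- if (!is.null(focal_mask_path)) read_mask(focal_mask_path, "focal")
  protected <- if (!is.null(protected_mask_path))
    read_mask(protected_mask_path, "protected")
  landscape_stack(features, analysis, focal_mask = focal,
                  protected_mask = protected)
}
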