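#' Proportion of a feature's distribution inside a region
#'
#' @param feature A [normalized_feature()].
#' @param region A [region_mask()] on the same grid.
#' @return Proportion in `[0, 1]` (the sum of the feature's per-cell
#'   proportions over member cells).
#' @export
overlap_fraction <- function(feature, region) {
  check_same_grid(feature$grid, region$grid, "feature and region")
  sum(feature$q[region$member])
}

#' Expected coverage under randomly placed protection
#'
#' The analytic expectation of [overlap_fraction()] if the region were
#' placed uniformly at random over the analysis mask: simply the region's
#' share of analysis cells.
#'
#' @param region A [region_mask()], subset of `analysis`.
#' @param analysis The analysis [region_mask()].
#' @return Proportion in `[0, 1]`.
#' @export
random_baseline <- function(region, analysis) {
  check_same_grid(region$grid, analysis$grid, "region and analysis mask")
  n <- mask_size(analysis)
  if (n == 0L) uml_stop("analysis mask is empty", "empty_landscape_error")
  sum(region$member & analysis$member) / n
}

#' Per-feature coverage of a focal region versus the random baseline
#'
#' Computes each feature's overlap with the focal region, compares it with
#' the shared random-placement baseline (strict inequality: equality is not
#' "above"), and tallies how many features -- and how many species, a
#' species counting as covered if its best seasonal feature is -- do better
#' than random.
#'
#' @param features List of [normalized_feature()]s.
#' @param region Focal [region_mask()].
#' @param analysis Analysis [region_mask()].
#' @return A list with `records` (data frame: `feature_id`, `species_id`,
#'   `season`, `overlap`, `baseline`, `above_baseline`) and `summary` (counts
#'   and fractions above baseline, per feature and per species).
#' @export
coverage_vs_random <- function(features, region, analysis) {
  if (length(features) < 1L)
    uml_stop("need at least one feature", "invalid_parameter_error")
  baseline <- random_baseline(region, analysis)
  records <- data.frame(
    feature_id = vapply(features, function(f) f$feature_id, character(1)),
    species_id = vapply(features, function(f) f$species_id, character(1)),
    season = vapply(features, function(f) f$season_tag, character(1)),
    overlap = vapply(features, function(f) overlap_fraction(f, region),
                     numeric(1)),
    stringsAsFactors = FALSE)
  records$baseline <- baseline
  records$above_baseline <- records$overlap > baseline
  sp_above <- tapply(records$above_baseline, records$species_id, any)
  summary <- list(
    baseline = baseline,
    n_features = nrow(records),
    n_features_above = sum(records$above_baseline),
    frac_features_above = mean(records$above_baseline),
    n_species = length(sp_above),
    n_species_above = sum(sp_above),
    frac_species_above = mean(sp_above))
  list(records = records, summary = summary)
}

#' Paired t-test
#'
#' Two-sided paired t-test on `d = x - y`, reported with the 95% confidence
#' interval of the mean difference. Degenerate inputs follow a stated
#' convention: if all differences are identical and non-zero the test is
#' undefined (error); if all differences are zero, `t = 0`, `p = 1`.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list of class `uml_paired_t`: `mean_difference`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `ci_low`, `ci_high`, `n_pairs`.
#' @export
paired_t <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y))
    uml_stop("x and y must have equal length", "invalid_parameter_error")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L)
    uml_stop("paired t-test needs at least 2 complete pairs",
             "invalid_parameter_error")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) != 0)
      uml_stop("all differences identical and non-zero: t undefined",
               "degenerate_test_error")
    res <- list(mean_difference = 0, t_statistic = 0,
                degrees_of_freedom = n - 1L, p_value = 1,
                ci_low = 0, ci_high = 0, n_pairs = n)
    return(structure(res, class = "uml_paired_t"))
  }
  tt <- stats::t.test(x, y, paired = TRUE, conf.level = conf_level)
  structure(list(mean_difference = unname(tt$estimate),
                 t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value,
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                 n_pairs = n),
            class = "uml_paired_t")
}

#' @export
print.uml_paired_t <- function(x, ...) {
  cat(sprintf("paired t-test: mean diff %.4g (95%% CI %.4g..%.4g), t = %.4g, df = %g, p = %.4g\n",
              x$mean_difference, x$ci_low, x$ci_high, x$t_statistic,
              x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Equal-area comparison of current protection versus a prioritization
#'
#' Compares, feature by feature, the coverage provided by the current
#' protection estate (`current_region`) with the coverage achievable in the
#' same total area under a multi-species prioritization: the top-ranked
#' landscape fraction of `rank_map` equal to the current region's share of
#' analysis cells. Differences (prioritized minus current) are summarized
#' with a paired t-test.
#'
#' @param features List of [normalized_feature()]s.
#' @param current_region [region_mask()] of currently protected cells.
#' @param rank_map Rank map from [rank_landscape()].
#' @param analysis Analysis [region_mask()].
#' @return A list: `fraction` (the compared landscape fraction), `table`
#'   (data frame: `feature_id`, `current_coverage`, `prioritized_coverage`,
#'   `difference`) and `test` (a [paired_t()] result).
#' @export
equal_area_comparison <- function(features, current_region, rank_map,
                                  analysis) {
  check_same_grid(current_region$grid, rank_map$grid,
                  "current region and rank map")
  n <- mask_size(analysis)
  if (rank_map$n_analysis != n)
    uml_stop("rank map was built on a different number of analysis cells",
             "invalid_comparison_error")
  n_region <- sum(current_region$member & analysis$member)
  fraction <- n_region / n
  if (abs(round(fraction * n) - n_region) > 1e-6)
    uml_stop("landscape fraction does not match the current region",
             "invalid_comparison_error")
  current <- vapply(features, function(f) overlap_fraction(f, current_region),
                    numeric(1))
  prioritized <- coverage_at_fraction(rank_map, features, fraction)
  tab <- data.frame(
    feature_id = vapply(features, function(f) f$feature_id, character(1)),
    current_coverage = current,
    prioritized_coverage = unname(prioritized),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$difference <- tab$prioritized_coverage - tab$current_coverage
  list(fraction = fraction, table = tab,
       test = paired_t(tab$prioritized_coverage, tab$current_coverage))
}

#' Median coverage per group
#'
#' @param records Coverage records (data frame with `feature_id` and
#'   `overlap`), e.g. from [coverage_vs_random()].
#' @param groups Named character vector mapping `feature_id` to a group
#'   label (taxon, season, ...). Every feature must be labelled.
#' @return Named numeric vector of per-group median overlaps (even-sized
#'   groups take the mean of the two middle values).
#' @export
group_summary <- function(records, groups) {
  lab <- groups[records$feature_id]
  if (any(is.na(lab) | is.null(lab)))
    uml_stop("every feature needs a group label", "missing_label_error")
  out <- tapply(records$overlap, lab, median)
  out_v <- as.vector(out); names(out_v) <- names(out)
  out_v
}
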