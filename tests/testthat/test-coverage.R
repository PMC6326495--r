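make_line_feature <- function(w, grid, analysis, id = "f") {
  normalize_feature(raw_layer(matrix(w, 1, length(w)), grid, id), analysis)
}

test_that("overlap with a region sums the feature's proportions there", {
  g <- grid_spec(1, 3)
  analysis <- region_mask(matrix(TRUE, 1, 3), g)
  f <- make_line_feature(c(2, 3, 5), g, analysis)
  reg3 <- region_mask(matrix(c(FALSE, FALSE, TRUE), 1, 3), g)
  expect_equal(overlap_fraction(f, reg3), 0.5)
  expect_equal(overlap_fraction(f, analysis), 1.0)
  empty <- region_mask(matrix(FALSE, 1, 3), g)
  expect_equal(overlap_fraction(f, empty), 0.0)

  ## additive over disjoint regions
  reg12 <- region_mask(matrix(c(TRUE, TRUE, FALSE), 1, 3), g)
  expect_equal(overlap_fraction(f, reg12) + overlap_fraction(f, reg3), 1)

  g2 <- grid_spec(1, 4)
  expect_error(overlap_fraction(f, region_mask(matrix(TRUE, 1, 4), g2)),
               class = "grid_mismatch_error")
})

test_that("the random baseline is the region's share of analysis cells", {
  g <- grid_spec(20, 50)
  analysis <- region_mask(matrix(TRUE, 20, 50), g)
  member <- matrix(FALSE, 20, 50); member[seq_len(233)] <- TRUE
  region <- region_mask(member, g)
  expect_equal(random_baseline(region, analysis), 0.233)
  expect_equal(random_baseline(analysis, analysis), 1.0)
  none <- region_mask(matrix(FALSE, 20, 50), g)
  expect_error(random_baseline(region, none), class = "empty_landscape_error")
})

test_that("baseline equals the Monte-Carlo mean overlap of random features", {
  set.seed(99)
  g <- grid_spec(10, 10)
  analysis <- region_mask(matrix(TRUE, 10, 10), g)
  member <- matrix(runif(100) < 0.3, 10, 10)
  region <- region_mask(member, g)
  base <- random_baseline(region, analysis)
  overlaps <- replicate(1000, {
    v <- matrix(0, 10, 10); v[sample.int(100, 1)] <- 1
    overlap_fraction(normalize_feature(raw_layer(v, g, "r"), analysis),
                     region)
  })
  se <- sd(overlaps) / sqrt(length(overlaps))
  expect_lt(abs(mean(overlaps) - base), 3 * se)
})

test_that("above-random tallies use strict inequality, per feature and species", {
  ## 8 cells, 2 in the region: proportions are exact binary fractions, so
  ## the uniform feature's overlap equals the baseline exactly
  g <- grid_spec(1, 8)
  analysis <- region_mask(matrix(TRUE, 1, 8), g)
  region <- region_mask(matrix(c(rep(TRUE, 2), rep(FALSE, 6)), 1, 8), g)
  inside <- make_line_feature(c(1, 1, 0, 0, 0, 0, 0, 0), g, analysis, "in")
  uniform <- make_line_feature(rep(1, 8), g, analysis, "uni")
  outside <- make_line_feature(c(0, 0, 1, 1, 1, 1, 1, 1), g, analysis, "out")
  cv <- coverage_vs_random(list(inside, uniform, outside), region, analysis)
  expect_equal(cv$summary$baseline, 0.25)
  expect_equal(cv$records$above_baseline, c(TRUE, FALSE, FALSE))
  expect_equal(cv$summary$n_features_above, 1)

  ## a species is covered if its best seasonal feature is
  g10 <- grid_spec(1, 10)
  analysis10 <- region_mask(matrix(TRUE, 1, 10), g10)
  region10 <- region_mask(matrix(c(rep(TRUE, 3), rep(FALSE, 7)), 1, 10), g10)
  summer <- normalize_feature(raw_layer(matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
                                               1, 10), g10, "spA_summer"),
                              analysis10, species_id = "spA",
                              season_tag = "summer")
  winter <- normalize_feature(raw_layer(matrix(c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
                                               1, 10), g10, "spA_winter"),
                              analysis10, species_id = "spA",
                              season_tag = "winter")
  cv2 <- coverage_vs_random(list(summer, winter), region10, analysis10)
  expect_equal(cv2$summary$n_features_above, 1)
  expect_equal(cv2$summary$n_species, 1)
  expect_equal(cv2$summary$n_species_above, 1)
})

test_that("paired t-test matches the closed form and its conventions", {
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$mean_difference, 2, tolerance = 1e-9)
  expect_equal(r$t_statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(r$degrees_of_freedom, 2)
  expect_equal(r$p_value, 2 * stats::pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-9)
  expect_equal(round(r$p_value, 4), 0.0742)
  ## 95% CI from the same t distribution
  d <- c(1, 2, 3); half <- stats::qt(0.975, 2) * sd(d) / sqrt(3)
  expect_equal(r$ci_low, 2 - half, tolerance = 1e-9)
  expect_equal(r$ci_high, 2 + half, tolerance = 1e-9)

  sym <- paired_t(c(1, 2, 3), c(3, 2, 1))
  expect_equal(sym$mean_difference, 0)
  expect_equal(sym$t_statistic, 0)
  expect_equal(sym$p_value, 1)

  ## antisymmetry and shift invariance
  a <- paired_t(c(2, 4, 7), c(1, 1, 2))
  b <- paired_t(c(1, 1, 2), c(2, 4, 7))
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$p_value, b$p_value)
  shifted <- paired_t(c(2, 4, 7) + 5, c(1, 1, 2) + 5)
  expect_equal(a$t_statistic, shifted$t_statistic, tolerance = 1e-12)

  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3, 4)),
               class = "invalid_parameter_error")
  expect_error(paired_t(c(2, 3), c(1, 2)), class = "degenerate_test_error")
  zero <- paired_t(c(1, 2), c(1, 2))
  expect_equal(zero$t_statistic, 0)
  expect_equal(zero$p_value, 1)
})

test_that("equal-area comparison pairs current and prioritized coverage", {
  set.seed(55)
  stack <- random_stack(55, max_cells = 60, max_features = 4)
  g <- stack$grid
  n <- mask_size(stack$analysis_mask)
  ## current region: a random third of the analysis cells
  member <- matrix(FALSE, g$n_rows, g$n_cols)
  cells <- which(stack$analysis_mask$member)
  member[sample(cells, floor(n / 3))] <- TRUE
  current <- region_mask(member, g, "current")

  ## lock the current region into the top ranks
  lv <- matrix(0L, g$n_rows, g$n_cols); lv[current$member] <- 1L
  res <- rank_landscape(stack, prioritizer_config("CAZ"),
                        removal_mask(lv, g))
  eq <- equal_area_comparison(stack$features, current, res$rank_map,
                              stack$analysis_mask)
  ## the top-ranked equal-area set is exactly the current region
  expect_lt(max(abs(eq$table$difference)), 1e-9)
  expect_equal(eq$test$t_statistic, 0)

  ## an unconstrained ranking can only do at least as well on average
  res2 <- rank_landscape(stack, prioritizer_config("CAZ"))
  eq2 <- equal_area_comparison(stack$features, current, res2$rank_map,
                               stack$analysis_mask)
  expect_equal(eq2$fraction, floor(n / 3) / n)
  expect_true(all(eq2$table$prioritized_coverage >= -1e-12))

  ## a rank map from a different landscape size is refused
  small <- random_stack(7, max_cells = 20, max_features = 2)
  res3 <- rank_landscape(small, prioritizer_config("ABF"))
  expect_error(equal_area_comparison(stack$features, current, res3$rank_map,
                                     stack$analysis_mask),
               class = "umbrellar_error")
})

test_that("group medians follow the mean-of-middle convention", {
  records <- data.frame(feature_id = c("a", "b", "c", "d", "e"),
                        overlap = c(0.1, 0.3, 0.5, 0.2, 0.4))
  groups <- c(a = "g1", b = "g1", c = "g1", d = "g2", e = "g3")
  out <- group_summary(records, groups)
  expect_equal(unname(out["g1"]), 0.3)
  expect_equal(unname(out["g2"]), 0.2)  # single-member group
  two <- group_summary(records, c(a = "x", b = "x", c = "y", d = "y", e = "y"))
  expect_equal(unname(two["x"]), 0.2)   # mean of two middle values
  expect_error(group_summary(records, c(a = "g1")),
               class = "missing_label_error")
})
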