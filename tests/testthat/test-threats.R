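line_analysis <- function(n) {
  g <- grid_spec(1, n)
  list(grid = g, analysis = region_mask(matrix(TRUE, 1, n), g))
}

test_that("land-use threat masks flag habitat cells forecast to convert", {
  g <- grid_spec(1, 4)
  shrub <- 52; crop <- 82
  analysis <- region_mask(matrix(c(TRUE, TRUE, TRUE, FALSE), 1, 4), g)
  baseline <- raw_layer(matrix(rep(shrub, 4), 1, 4), g, "base")
  future <- raw_layer(matrix(c(crop, shrub, crop, crop), 1, 4), g, "fut")
  th <- lulc_threat_mask(future, crop, analysis, "A1B", baseline = baseline)
  ## shrub -> crop threatened; shrub -> shrub not; outside analysis never
  expect_equal(as.vector(th$member), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(th$threat_id, "lulc")
  expect_equal(th$scenario_id, "A1B")
  g2 <- grid_spec(2, 4)
  expect_error(lulc_threat_mask(raw_layer(matrix(crop, 2, 4), g2, "x"),
                                crop, analysis, "A1B"),
               class = "grid_mismatch_error")
})

test_that("invasion risk is the low resistance/resilience class only", {
  g <- grid_spec(1, 3)
  analysis <- region_mask(matrix(TRUE, 1, 3), g)
  rr <- raw_layer(matrix(c(1, 2, 3), 1, 3), g, "rr")  # low, moderate, high
  th <- cheatgrass_risk_mask(rr, analysis)
  expect_equal(as.vector(th$member), c(TRUE, FALSE, FALSE))
  expect_equal(th$threat_id, "cheatgrass")
  bad <- raw_layer(matrix(c(1, 2, 9), 1, 3), g, "rr")
  expect_error(cheatgrass_risk_mask(bad, analysis),
               class = "invalid_class_error")
})

test_that("exposure splits a feature's mass by threat, inside and out", {
  la <- line_analysis(3)
  f <- normalize_feature(raw_layer(matrix(c(2, 3, 5), 1, 3), la$grid, "f"),
                         la$analysis)
  threat <- threat_mask(matrix(c(FALSE, FALSE, TRUE), 1, 3), la$grid,
                        "lulc", "A1B")
  focal <- region_mask(matrix(c(TRUE, TRUE, FALSE), 1, 3), la$grid, "focal")
  e <- exposure(f, threat, focal)
  expect_equal(e$exposure_region, 0.5)
  expect_equal(e$exposure_focal, 0.0)

  none <- threat_mask(matrix(FALSE, 1, 3), la$grid, "lulc", "A1B")
  all_th <- threat_mask(matrix(TRUE, 1, 3), la$grid, "lulc", "A1B")
  expect_equal(exposure(f, none, focal)$exposure_region, 0)
  expect_equal(exposure(f, none, focal)$exposure_focal, 0)
  expect_equal(exposure(f, all_th, focal)$exposure_region, 1)
  expect_equal(exposure(f, all_th, focal)$exposure_focal, 1)

  ## zero mass inside the focal region: conditional exposure undefined
  f_out <- normalize_feature(raw_layer(matrix(c(0, 0, 5), 1, 3), la$grid,
                                       "f2"), la$analysis)
  e2 <- exposure(f_out, threat, focal)
  expect_true(is.na(e2$exposure_focal))
  expect_false(e2$focal_defined)
})

test_that("exposure is monotone under threat-mask union", {
  set.seed(71)
  la <- line_analysis(40)
  f <- normalize_feature(raw_layer(matrix(runif(40), 1, 40), la$grid, "f"),
                         la$analysis)
  focal <- region_mask(matrix(runif(40) < 0.4, 1, 40), la$grid, "focal")
  a <- runif(40) < 0.2
  b <- a | (runif(40) < 0.2)  # superset of a
  th_a <- threat_mask(matrix(a, 1, 40), la$grid, "lulc", "s1")
  th_b <- threat_mask(matrix(b, 1, 40), la$grid, "lulc", "s2")
  ea <- exposure(f, th_a, focal); eb <- exposure(f, th_b, focal)
  expect_lte(ea$exposure_region, eb$exposure_region)
  if (!is.na(ea$exposure_focal))
    expect_lte(ea$exposure_focal, eb$exposure_focal)
})

test_that("every threat mask is applied to every feature", {
  set.seed(72)
  la <- line_analysis(20)
  features <- lapply(1:3, function(j)
    normalize_feature(raw_layer(matrix(runif(20), 1, 20), la$grid,
                                sprintf("f%d", j)), la$analysis))
  threats <- lapply(1:2, function(s)
    threat_mask(matrix(runif(20) < 0.3, 1, 20), la$grid, "lulc",
                sprintf("s%d", s)))
  focal <- region_mask(matrix(runif(20) < 0.4, 1, 20), la$grid, "focal")
  tab <- exposure_table(features, threats, focal)
  expect_equal(nrow(tab), 6)
  expect_equal(sort(unique(tab$feature_id)), c("f1", "f2", "f3"))
  expect_equal(sort(unique(tab$scenario_id)), c("s1", "s2"))
})

test_that("scenario summaries reproduce closed-form landscape statistics", {
  ## 200 analysis cells, 100 focal; four scenarios with landscape exposure
  ## inside (0.04, 0.05, 0.05, 0.06) vs whole region (0.10, 0.11, 0.12, 0.13)
  g <- grid_spec(10, 20)
  analysis <- region_mask(matrix(TRUE, 10, 20), g)
  member <- matrix(FALSE, 10, 20); member[, 1:10] <- TRUE  # 100 focal cells
  focal <- region_mask(member, g, "focal")
  inside_cells <- c(4, 5, 5, 6)              # /100 -> 0.04 0.05 0.05 0.06
  region_cells <- c(20, 22, 24, 26)          # /200 -> 0.10 0.11 0.12 0.13
  focal_idx <- which(member); outside_idx <- which(!member)
  threats <- lapply(1:4, function(s) {
    m <- matrix(FALSE, 10, 20)
    m[focal_idx[seq_len(inside_cells[s])]] <- TRUE
    m[outside_idx[seq_len(region_cells[s] - inside_cells[s])]] <- TRUE
    threat_mask(m, g, "lulc", sprintf("s%d", s))
  })
  set.seed(73)
  features <- lapply(1:3, function(j)
    normalize_feature(raw_layer(matrix(runif(200), 10, 20), g,
                                sprintf("f%d", j)), analysis))
  tab <- exposure_table(features, threats, focal)
  s <- scenario_summary(tab, threats, focal, analysis)$lulc

  expect_equal(s$per_scenario$landscape_exposure_focal,
               c(0.04, 0.05, 0.05, 0.06))
  expect_equal(s$per_scenario$landscape_exposure_region,
               c(0.10, 0.11, 0.12, 0.13))
  ## closed-form paired t across scenarios
  d <- c(0.04, 0.05, 0.05, 0.06) - c(0.10, 0.11, 0.12, 0.13)
  t_expected <- mean(d) / (sd(d) / 2)
  expect_equal(s$scenario_test$mean_difference, -0.065, tolerance = 1e-12)
  expect_equal(s$scenario_test$t_statistic, t_expected, tolerance = 1e-9)
  expect_equal(s$scenario_test$degrees_of_freedom, 3)
  ## feature-level test pairs scenario-averaged exposures
  expect_equal(s$feature_test$n_pairs, 3)

  ## identical scenarios: zero spread across scenarios
  same <- lapply(1:3, function(s2) {
    m <- matrix(FALSE, 10, 20); m[focal_idx[1:5]] <- TRUE
    threat_mask(m, g, "lulc", sprintf("t%d", s2))
  })
  tab2 <- exposure_table(features, same, focal)
  s2 <- scenario_summary(tab2, same, focal, analysis)$lulc
  expect_equal(s2$se_landscape_exposure_focal, 0)
  expect_equal(s2$se_landscape_exposure_region, 0)
})
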