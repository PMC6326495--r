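## direct arithmetic evaluation of the two marginal-loss rules, used as the
## independent check on the package implementations
abf_direct <- function(qjn, qji, cost = 1, z = 0.25) {
  sum(qjn^z - (qjn - qji)^z) / cost
}
caz_direct <- function(qjn, qji, cost = 1) {
  r <- ifelse(qjn > 0, qji / qjn, 0)
  max(r, 0) / cost
}

test_that("additive-benefit marginal loss matches direct arithmetic", {
  ## single feature spread 0.2 per cell: q_jn = 1, q_ji = 0.2
  stack <- row_stack(rep(1, 5))
  state <- umbrellar:::prioritizer_state(stack)
  d <- marginal_loss_abf(state, 1)
  expect_equal(d, 1 - 0.8^0.25, tolerance = 1e-12)
  expect_equal(round(d, 5), 0.05426)

  ## cell holding all remaining mass of the feature: q_jn = q_ji = 0.5
  stack2 <- row_stack(c(0.5, 0.3, 0.2))
  state2 <- umbrellar:::prioritizer_state(stack2)
  state2$qjn <- state2$qjn - state2$Q[, 2] - state2$Q[, 3]
  state2$remaining[2:3] <- FALSE
  expect_equal(marginal_loss_abf(state2, 1), 0.5^0.25, tolerance = 1e-12)

  ## a cell empty for every feature loses nothing
  stack3 <- row_stack(c(0, 2, 3), c(0, 1, 4))
  state3 <- umbrellar:::prioritizer_state(stack3)
  expect_equal(marginal_loss_abf(state3, 1), 0)

  ## multi-feature, non-unit cost, arbitrary z
  stack4 <- row_stack(c(1, 2, 7), c(5, 3, 2), cost = c(2, 1, 1))
  state4 <- umbrellar:::prioritizer_state(stack4)
  expect_equal(marginal_loss_abf(state4, 1, z_exponent = 0.4),
               abf_direct(c(1, 1), c(0.1, 0.5), cost = 2, z = 0.4),
               tolerance = 1e-12)
})

test_that("core-area marginal loss takes the worst-feature ratio", {
  stack <- row_stack(c(1, 9), c(4, 6))  # ratios in cell 1: 0.1 and 0.4
  state <- umbrellar:::prioritizer_state(stack)
  expect_equal(marginal_loss_caz(state, 1), 0.4, tolerance = 1e-12)

  stack2 <- row_stack(c(0, 1, 1), c(0, 2, 2))
  expect_equal(marginal_loss_caz(umbrellar:::prioritizer_state(stack2), 1), 0)

  ## cell holding a feature's entire remaining distribution
  stack3 <- row_stack(c(10, 0, 0), c(1, 1, 2))
  expect_equal(marginal_loss_caz(umbrellar:::prioritizer_state(stack3), 1), 1)

  ## a fully-removed feature contributes ratio 0, not 0/0
  state3 <- umbrellar:::prioritizer_state(stack3)
  state3$qjn[1] <- 0
  state3$Q[1, ] <- 0
  expect_equal(marginal_loss_caz(state3, 2), 0.25, tolerance = 1e-12)
})

test_that("marginal-loss functions validate their cell argument", {
  stack <- row_stack(c(1, 2, 3))
  state <- umbrellar:::prioritizer_state(stack)
  expect_error(marginal_loss_abf(state, 9), class = "invalid_cell_error")
  state$remaining[2] <- FALSE
  expect_error(marginal_loss_abf(state, 2), class = "invalid_cell_error")
  state$qjn <- state$qjn - 0.9  # corrupted bookkeeping
  expect_error(marginal_loss_abf(state, 1), class = "state_corruption_error")
  expect_error(marginal_loss_caz(state, 1), class = "state_corruption_error")
})

test_that("a 1x3 landscape is ranked in ascending feature-weight order", {
  stack <- row_stack(c(2, 3, 5))  # q = 0.2, 0.3, 0.5
  res <- rank_landscape(stack, prioritizer_config("ABF"))
  expect_equal(rank_positions(res), c(1, 2, 3))
  expect_equal(as.vector(res$rank_map$rank_fraction), c(1, 2, 3) / 3)

  ## masking cell 1 to level 1 forces it to the top rank
  rmask <- removal_mask(matrix(c(1, 0, 0), 1, 3), stack$grid)
  res_m <- rank_landscape(stack, prioritizer_config("ABF"), rmask)
  expect_equal(rank_positions(res_m), c(2, 3, 1))
  expect_equal(res_m$rank_map$rank_fraction[1, 1], 1)

  ## coverage of the top-ranked fractions of the unmasked run
  f <- stack$features
  expect_equal(unname(coverage_at_fraction(res$rank_map, f, 1)), 1)
  expect_equal(unname(coverage_at_fraction(res$rank_map, f, 0)), 0)
  expect_equal(unname(coverage_at_fraction(res$rank_map, f, 2 / 3)), 0.8)
  expect_equal(unname(coverage_at_fraction(res$rank_map, f, 1 / 3)), 0.5)
  expect_error(coverage_at_fraction(res$rank_map, f, 1.2),
               class = "invalid_parameter_error")

  ## performance of the feature at retained fraction 1/3: only cell 3 left
  perf <- res$performance
  expect_equal(perf$proportion_retained[abs(perf$fraction_retained - 1/3) < 1e-12],
               0.5)
})

test_that("single-feature ABF removal order sorts cells by weight then index", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 12
    w <- sample(0:4, n, replace = TRUE)
    if (sum(w) == 0) w[1] <- 1
    stack <- row_stack(w)
    res <- rank_landscape(stack, prioritizer_config("ABF"))
    expect_equal(rank_positions(res), order(w, seq_len(n)))
  }
})

test_that("CAZ keeps a feature's last stronghold until the end", {
  ## cell 4 holds 100% of feature 2
  stack <- row_stack(c(3, 2, 4, 1), c(0, 0, 0, 5))
  res <- rank_landscape(stack, prioritizer_config("CAZ"))
  expect_equal(rank_positions(res)[4], 4)
  ## duplicate features do not change a CAZ ranking (max is duplicate-proof)
  stack_dup <- row_stack(c(3, 2, 4, 1), c(0, 0, 0, 5), c(0, 0, 0, 5))
  res_dup <- rank_landscape(stack_dup, prioritizer_config("CAZ"))
  expect_equal(rank_positions(res_dup), rank_positions(res))
})

test_that("rank maps are valid permutations and deterministic", {
  for (seed in c(3, 17)) {
    stack <- random_stack(seed)
    for (obj in c("ABF", "CAZ")) {
      res <- rank_landscape(stack, prioritizer_config(obj))
      fr <- fractions_on_analysis(stack, res$rank_map)
      n <- mask_size(stack$analysis_mask)
      expect_equal(sort(fr), seq_len(n) / n)
      res2 <- rank_landscape(stack, prioritizer_config(obj))
      expect_identical(res$rank_map$rank_fraction,
                       res2$rank_map$rank_fraction)
    }
  }
})

test_that("warp batches remove several cells per evaluation and stay valid", {
  stack <- random_stack(33)
  rmask <- random_levels(stack, 34)
  res <- rank_landscape(stack, prioritizer_config("ABF", warp = 4), rmask)
  n <- mask_size(stack$analysis_mask)
  fr <- fractions_on_analysis(stack, res$rank_map)
  expect_equal(sort(fr), seq_len(n) / n)
  ## mask hierarchy survives batching
  lv <- levels_on_analysis(stack, rmask)
  for (k in sort(unique(lv))[-1])
    expect_gt(min(fr[lv == k]), max(fr[lv < k]))
})

test_that("performance curves are monotone with exact endpoints", {
  stack <- random_stack(8)
  res <- rank_landscape(stack, prioritizer_config("CAZ"))
  perf <- res$performance
  for (fid in unique(perf$feature_id)) {
    p <- perf[perf$feature_id == fid, ]
    p <- p[order(p$fraction_retained), ]
    expect_true(all(diff(p$proportion_retained) >= -1e-12))
    expect_true(all(p$proportion_retained >= -1e-12 &
                      p$proportion_retained <= 1 + 1e-12))
    expect_equal(p$proportion_retained[p$fraction_retained == 1], 1)
    expect_lt(abs(p$proportion_retained[p$fraction_retained == 0]), 1e-9)
  }
})

test_that("degenerate landscapes are handled", {
  g <- grid_spec(1, 1)
  analysis <- region_mask(matrix(TRUE, 1, 1), g)
  f <- normalize_feature(raw_layer(matrix(2, 1, 1), g, "f"), analysis)
  stack <- landscape_stack(list(f), analysis)
  res <- rank_landscape(stack, prioritizer_config("ABF"))
  expect_equal(res$rank_map$rank_fraction[1, 1], 1)
  res_ref <- rank_landscape_reference(stack, prioritizer_config("ABF"))
  expect_equal(res_ref$rank_map$rank_fraction[1, 1], 1)
  expect_error(prioritizer_config("ABF", warp = 0),
               class = "invalid_parameter_error")
  expect_error(prioritizer_config("ABF", z_exponent = 0),
               class = "invalid_parameter_error")
})
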