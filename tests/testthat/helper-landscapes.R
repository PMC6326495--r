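## Fixture builders shared across the test files. Everything is generated in
## code; no on-disk fixtures.

## a 1 x n stack from raw per-cell weights (one row per feature)
row_stack <- function(..., cost = NULL) {
  qs <- list(...)
  n <- length(qs[[1]])
  grid <- grid_spec(1, n)
  analysis <- region_mask(matrix(TRUE, 1, n), grid, "analysis")
  features <- lapply(seq_along(qs), function(j) {
    normalize_feature(raw_layer(matrix(qs[[j]], 1, n), grid,
                                sprintf("f%d", j)), analysis)
  })
  landscape_stack(features, analysis,
                  cost = if (is.null(cost)) NULL else matrix(cost, 1, n))
}

## random stack on a small grid: random mask, 1..max_features features with
## patchy non-negative weights (zeros common, so ties and absent features
## are exercised)
random_stack <- function(seed, max_cells = 100, max_features = 5) {
  set.seed(seed)
  repeat {
    nr <- sample(2:10, 1); nc <- sample(2:(max_cells %/% nr), 1)
    grid <- grid_spec(nr, nc)
    member <- matrix(runif(nr * nc) < 0.8, nr, nc)
    if (sum(member) >= 3) break
  }
  analysis <- region_mask(member, grid, "analysis")
  nf <- sample(1:max_features, 1)
  features <- vector("list", nf)
  for (j in seq_len(nf)) {
    repeat {
      v <- matrix(round(runif(nr * nc), 2) * (runif(nr * nc) < 0.6), nr, nc)
      v[!member] <- 0
      if (sum(v) > 0) break
    }
    features[[j]] <- normalize_feature(raw_layer(v, grid, sprintf("f%d", j)),
                                       analysis)
  }
  landscape_stack(features, analysis)
}

## random hierarchical removal mask (levels 0..2) on a stack's grid
random_levels <- function(stack, seed) {
  set.seed(seed)
  g <- stack$grid
  removal_mask(matrix(sample(0:2, g$n_rows * g$n_cols, replace = TRUE),
                      g$n_rows, g$n_cols), g)
}

## removal-rank positions (row-major, analysis cells only) of a rank result
rank_positions <- function(res) res$removal_order

## mask levels aligned to the analysis-cell ordering of a stack
levels_on_analysis <- function(stack, rmask) {
  member <- as.vector(t(stack$analysis_mask$member))
  as.vector(t(rmask$level))[which(member)]
}

## rank fractions aligned to the analysis-cell ordering
fractions_on_analysis <- function(stack, rank_map) {
  member <- as.vector(t(stack$analysis_mask$member))
  as.vector(t(rank_map$rank_fraction))[which(member)]
}
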