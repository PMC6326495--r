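#' Prioritizer configuration
#'
#' @param objective `"ABF"` (additive benefit: favors species-rich cells) or
#'   `"CAZ"` (core-area: favors cells important to any single feature).
#' @param z_exponent Power applied to remaining proportions under ABF;
#'   default 0.25, must lie in `(0, 1]`.
#' @param warp Cells removed per marginal-loss evaluation. 1 (default) is
#'   the exact greedy algorithm; larger values approximate it in batches.
#' @param tie_break Only `"lowest_index"` is implemented: equal marginal
#'   losses are resolved by removing the lowest row-major cell index first,
#'   making every run deterministic.
#' @param seed Reserved; the default algorithm draws no random numbers.
#' @return An object of class `uml_priocfg`.
#' @export
prioritizer_config <- function(objective = c("ABF", "CAZ"), z_exponent = 0.25,
                               warp = 1L, tie_break = "lowest_index",
                               seed = NULL) {
  objective <- match.arg(objective)
  if (!is.numeric(z_exponent) || z_exponent <= 0 || z_exponent > 1)
    uml_stop("z_exponent must lie in (0, 1]", "invalid_parameter_error")
  warp <- as.integer(warp)
  if (is.na(warp) || warp < 1L)
    uml_stop("warp must be a positive integer", "invalid_parameter_error")
  if (!identical(tie_break, "lowest_index"))
    uml_stop("only tie_break = 'lowest_index' is implemented",
             "invalid_parameter_error")
  structure(list(objective = objective, z_exponent = z_exponent, warp = warp,
                 tie_break = tie_break, seed = seed), class = "uml_priocfg")
}

#' Hierarchical removal mask
#'
#' Per-cell non-negative integer levels. All cells of level `k` are removed
#' from the landscape before any cell of level `k + 1`, so higher levels are
#' guaranteed the top ranks. Used to lock protected areas (and, in
#' outside-focal scenarios, focal areas) into the best part of the ranking.
#'
#' @param level Integer matrix of levels (default all zero).
#' @param grid A [grid_spec()].
#' @return An object of class `uml_removal`.
#' @export
removal_mask <- function(level, grid) {
  level <- as.matrix(level)
  if (nrow(level) != grid$n_rows || ncol(level) != grid$n_cols)
    uml_stop("level matrix does not match grid dimensions",
             "grid_mismatch_error")
  if (any(is.na(level)) || any(level < 0) || any(level != round(level)))
    uml_stop("removal-mask levels must be non-negative integers",
             "invalid_parameter_error")
  structure(list(grid = grid, level = matrix(as.integer(level), nrow(level))),
            class = "uml_removal")
}

## Internal: dense per-analysis-cell view of a stack, shared by the compiled
## ranker, the naive reference, and the marginal-loss functions.
## Analysis cells are ordered by row-major linear index; `cell` arguments
## index into that ordering (1-based).
prioritizer_state <- function(stack, removal_mask = NULL) {
  member <- rm_vec(stack$analysis_mask$member)
  cells <- which(member)
  N <- length(cells)
  F_ <- length(stack$features)
  Q <- matrix(0, F_, N)
  for (j in seq_len(F_)) Q[j, ] <- rm_vec(stack$features[[j]]$q)[cells]
  level <- rep(0L, N)
  if (!is.null(removal_mask)) {
    check_same_grid(removal_mask$grid, stack$grid, "removal mask and stack")
    level <- rm_vec(removal_mask$level)[cells]
  }
  structure(list(Q = Q, qjn = rowSums(Q), cost = rm_vec(stack$cost)[cells],
                 level = level, remaining = rep(TRUE, N), cells = cells,
                 feature_ids = feature_ids(stack), grid = stack$grid),
            class = "uml_state")
}

check_cell_remaining <- function(state, cell) {
  if (!is.numeric(cell) || length(cell) != 1L || is.na(cell) ||
      cell < 1 || cell > ncol(state$Q))
    uml_stop("cell index out of range", "invalid_cell_error")
  if (!state$remaining[cell])
    uml_stop("cell has already been removed", "invalid_cell_error")
  invisible(TRUE)
}

#' Additive-benefit marginal loss of one cell
#'
#' The drop in power-transformed representation summed over features when
#' cell `i` is removed from the remaining set:
#' `(1 / c_i) * sum_j [ q_jn^z - (q_jn - q_ji)^z ]`.
#'
#' @param state A prioritizer state (see [rank_landscape_reference()]).
#' @param cell 1-based index into the analysis cells (row-major order).
#' @param z_exponent Power parameter, default 0.25.
#' @return Non-negative marginal loss.
#' @export
marginal_loss_abf <- function(state, cell, z_exponent = 0.25) {
  check_cell_remaining(state, cell)
  qji <- state$Q[, cell]
  rem <- state$qjn - qji
  if (any(rem < -1e-9))
    uml_stop("state corruption: q_jn - q_ji < -1e-9", "state_corruption_error")
  rem[rem < 0] <- 0
  sum(pmax(state$qjn, 0)^z_exponent - rem^z_exponent) / state$cost[cell]
}

#' Core-area marginal loss of one cell
#'
#' The largest per-feature proportional loss in the cell:
#' `(1 / c_i) * max_j q_ji / q_jn`, with the ratio defined as 0 for features
#' whose remaining proportion `q_jn` is 0.
#'
#' @inheritParams marginal_loss_abf
#' @return Marginal loss in `[0, 1 / c_i]`.
#' @export
marginal_loss_caz <- function(state, cell) {
  check_cell_remaining(state, cell)
  qji <- state$Q[, cell]
  if (any(state$qjn - qji < -1e-9))
    uml_stop("state corruption: q_jn - q_ji < -1e-9", "state_corruption_error")
  ratio <- ifelse(state$qjn > 0, qji / state$qjn, 0)
  max(ratio, 0) / state$cost[cell]
}

## Internal: assemble the RankMap + PerformanceTable return value from a
## removal order (1-based positions into state$cells) and the q_jn
## trajectory (one row per removal).
build_rank_result <- function(state, order, traj) {
  N <- length(order)
  grid <- state$grid
  rank_frac <- rep(NA_real_, grid$n_rows * grid$n_cols)
  rank_frac[state$cells[order]] <- seq_len(N) / N
  rank_map <- structure(list(grid = grid,
                             rank_fraction = rm_mat(rank_frac, grid),
                             n_analysis = N),
                        class = "uml_rankmap")
  fid <- state$feature_ids
  traj[traj < 0] <- 0
  performance <- data.frame(
    fraction_retained = rep(c(1, (N - seq_len(N)) / N), times = length(fid)),
    feature_id = rep(fid, each = N + 1L),
    proportion_retained = as.vector(rbind(1, traj)),
    stringsAsFactors = FALSE)
  list(rank_map = rank_map, performance = performance,
       removal_order = state$cells[order])
}

#' @export
print.uml_rankmap <- function(x, ...) {
  cat(sprintf("<rank map %d x %d, %d ranked analysis cells>\n",
              x$grid$n_rows, x$grid$n_cols, x$n_analysis))
  invisible(x)
}

#' Rank a landscape by greedy cell removal
#'
#' Iteratively removes the cell with the smallest marginal loss under the
#' configured objective (ties broken by lowest row-major cell index),
#' honouring the hierarchical removal mask: cells of a higher mask level are
#' only touched once every lower-level cell is gone, so they always end up
#' with the highest ranks. Returns the per-cell removal-rank fraction (first
#' removed = `1/N`, last = `1`) and the per-feature performance table: the
#' proportion of each feature retained at every landscape fraction.
#'
#' @param stack A [landscape_stack()].
#' @param config A [prioritizer_config()].
#' @param removal_mask Optional [removal_mask()]; `NULL` means a flat
#'   landscape (all level 0).
#' @return A list with elements `rank_map` (class `uml_rankmap`),
#'   `performance` (long data frame: `fraction_retained`, `feature_id`,
#'   `proportion_retained`) and `removal_order` (row-major analysis-cell
#'   positions in removal order).
#' @export
rank_landscape <- function(stack, config = prioritizer_config(),
                           removal_mask = NULL) {
  state <- prioritizer_state(stack, removal_mask)
  if (ncol(state$Q) == 0L)
    uml_stop("analysis mask is empty", "empty_landscape_error")
  res <- .greedy_rank_cpp(state$Q, state$qjn, state$cost, state$level,
                          config$z_exponent, config$warp,
                          if (config$objective == "ABF") 0L else 1L, TRUE)
  build_rank_result(state, res$order, res$trajectory)
}

#' Naive reference ranking (independent oracle)
#'
#' Same contract as [rank_landscape()], but implemented as a plain R loop
#' that re-evaluates the marginal loss of every remaining cell at every
#' iteration via [marginal_loss_abf()] / [marginal_loss_caz()], with no
#' incremental shortcuts. Intended for small grids (up to ~10,000 cells) and
#' used as the equivalence oracle in tests. Only `warp = 1` is supported.
#'
#' @inheritParams rank_landscape
#' @return As [rank_landscape()].
#' @export
rank_landscape_reference <- function(stack, config = prioritizer_config(),
                                     removal_mask = NULL) {
  if (config$warp != 1L)
    uml_stop("the reference implementation supports warp = 1 only",
             "invalid_parameter_error")
  state <- prioritizer_state(stack, removal_mask)
  N <- ncol(state$Q)
  if (N == 0L) uml_stop("analysis mask is empty", "empty_landscape_error")
  F_ <- nrow(state$Q)
  loss_fun <- if (config$objective == "ABF") {
    function(s, i) marginal_loss_abf(s, i, config$z_exponent)
  } else {
    marginal_loss_caz
  }
  order_out <- integer(N)
  traj <- matrix(0, N, F_)
  k <- 0L
  for (lv in sort(unique(state$level))) {
    repeat {
      idx <- which(state$remaining & state$level == lv)
      if (length(idx) == 0L) break
      delta <- vapply(idx, function(i) loss_fun(state, i), numeric(1))
      pick <- idx[which.min(delta)]  # first minimum = lowest index
      state$remaining[pick] <- FALSE
      state$qjn <- state$qjn - state$Q[, pick]
      state$qjn[state$qjn < 0] <- 0
      k <- k + 1L
      order_out[k] <- pick
      traj[k, ] <- state$qjn
    }
  }
  build_rank_result(state, order_out, traj)
}

#' Per-feature coverage of the top-ranked landscape fraction
#'
#' For each feature, the proportion of its distribution falling in the
#' best-ranked `fraction` of the landscape (cells with
#' `rank_fraction > 1 - fraction`).
#'
#' @param rank_map A rank map from [rank_landscape()].
#' @param features List of [normalized_feature()]s on the same grid.
#' @param fraction Landscape fraction retained, in `[0, 1]`.
#' @return Named numeric vector of proportions retained, one per feature.
#' @export
coverage_at_fraction <- function(rank_map, features, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1)
    uml_stop("fraction must lie in [0, 1]", "invalid_parameter_error")
  rf <- rank_map$rank_fraction
  retained <- !is.na(rf) & rf > (1 - fraction) + 1e-12
  out <- vapply(features, function(f) {
    check_same_grid(f$grid, rank_map$grid, "feature and rank map")
    sum(f$q[retained])
  }, numeric(1))
  names(out) <- vapply(features, function(f) f$feature_id, character(1))
  out
}
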