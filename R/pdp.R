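# Exact Friedman partial dependence for one piecewise-constant tree.
# Rather than re-predicting the whole panel once per grid value, the tree is
# traversed once: splits on features other than the target partition the
# panel rows, splits on the target feature partition the grid. Every
# (row subset, grid subset) pair reaching a leaf contributes
# leaf_value * n_rows to the accumulator of those grid points, which equals
# the brute-force average exactly.
pdp_tree_sums <- function(tree, Xm, j_pdp, grid) {
  acc <- numeric(length(grid))
  stack <- list(list(node = 1L, idx = seq_len(nrow(Xm)),
                     g = seq_along(grid)))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node
    j <- tree$feature[node]
    if (is.na(j)) {
      acc[fr$g] <- acc[fr$g] + tree$value[node] * length(fr$idx)
    } else if (j == j_pdp) {
      gl <- grid[fr$g] <= tree$threshold[node]
      if (any(gl))
        stack[[length(stack) + 1L]] <- list(node = tree$left[node],
                                            idx = fr$idx, g = fr$g[gl])
      if (!all(gl))
        stack[[length(stack) + 1L]] <- list(node = tree$right[node],
                                            idx = fr$idx, g = fr$g[!gl])
    } else {
      xv <- Xm[fr$idx, j]
      gl <- if (tree$meta$is_cat[j]) xv %in% tree$cats[[node]]
            else xv <= tree$threshold[node]
      if (any(gl))
        stack[[length(stack) + 1L]] <- list(node = tree$left[node],
                                            idx = fr$idx[gl], g = fr$g)
      if (!all(gl))
        stack[[length(stack) + 1L]] <- list(node = tree$right[node],
                                            idx = fr$idx[!gl], g = fr$g)
    }
  }
  acc
}

#' Friedman partial-dependence curve
#'
#' The curve value at grid point g is the mean, over every row of `panel`,
#' of the model prediction with `feature` forcibly set to g and all other
#' columns untouched. The default grid is the sorted unique observed values
#' of the feature, capped at `max_grid` quantile points. Works for
#' `regression_tree` and `random_forest` models (for a forest the curve is
#' the mean of the member trees' curves, which equals the forest's Friedman
#' average). The target feature must be numeric.
#'
#' @param model a `regression_tree` or `random_forest`.
#' @param panel data.frame over which to average (every feature column
#'   present; need not be the training data).
#' @param feature name of the numeric feature to vary.
#' @param grid optional strictly increasing numeric grid; default derived
#'   from the observed values.
#' @param max_grid cap on the default grid size (quantile-thinned).
#' @return a data.frame of class `pdp_curve` with columns `grid`, `value`
#'   and attributes `feature` and `baseline` (the curve mean).
#' @export
partial_dependence <- function(model, panel, feature, grid = NULL,
                               max_grid = 256L) {
  if (!is.data.frame(panel) || nrow(panel) == 0L)
    stop("panel must be a non-empty data.frame")
  meta <- model$meta
  j_pdp <- match(feature, meta$feature_names)
  if (is.na(j_pdp)) stop("feature '", feature, "' is not a model input")
  if (meta$is_cat[j_pdp])
    stop("partial dependence is defined here for numeric features only")
  if (is.null(grid)) {
    v <- sort(unique(as.numeric(panel[[feature]])))
    grid <- if (length(v) > max_grid)
      sort(unique(stats::quantile(v, probs = seq(0, 1, length.out = max_grid),
                                  names = FALSE, type = 7)))
    else v
  }
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("grid must be non-empty")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  Xm <- encode_new_data(meta, panel)
  n <- nrow(Xm)
  if (inherits(model, "regression_tree")) {
    value <- pdp_tree_sums(model, Xm, j_pdp, grid) / n
  } else if (inherits(model, "random_forest")) {
    acc <- numeric(length(grid))
    for (b in seq_len(model$n_trees))
      acc <- acc + pdp_tree_sums(forest_tree(model, b), Xm, j_pdp, grid)
    value <- acc / (n * model$n_trees)
  } else {
    stop("model must be a regression_tree or random_forest")
  }
  out <- data.frame(grid = grid, value = value)
  attr(out, "feature") <- feature
  attr(out, "baseline") <- mean(value)
  class(out) <- c("pdp_curve", "data.frame")
  out
}

#' Percent change per exposure increment implied by a PDP curve
#'
#' Summarizes a partial-dependence curve as the least-squares slope of its
#' values over the grid, scaled to an exposure increment (10 ug/m3 for
#' PM2.5) and normalized by the curve mean:
#' `100 * slope * increment / mean(value)`.
#'
#' @param curve a `pdp_curve` with at least 2 grid points.
#' @param increment exposure increment, default 10.
#' @return percent change per increment.
#' @export
pdp_effect_size <- function(curve, increment = 10) {
  if (nrow(curve) < 2L) stop("need at least 2 grid points")
  baseline <- mean(curve$value)
  if (abs(baseline) < .Machine$double.eps) stop("zero curve baseline")
  g <- curve$grid - mean(curve$grid)
  slope <- sum(g * curve$value) / sum(g^2)
  100 * slope * increment / baseline
}

#' Write a PDP curve as CSV
#'
#' @param curve a `pdp_curve`.
#' @param path output path; columns `grid,value`.
#' @return `path`, invisibly.
#' @export
write_pdp_csv <- function(curve, path) {
  utils::write.csv(data.frame(grid = signif(curve$grid, 6),
                              value = signif(curve$value, 6)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
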