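#' Fit a bootstrap random forest of regression trees
#'
#' Bagged ensemble: each tree is grown on a with-replacement bootstrap
#' sample of size n (unless `bootstrap = FALSE`), with `mtry` features
#' sampled uniformly at each split. The forest prediction is the arithmetic
#' mean of the member trees' predictions. The default ensemble size of 500
#' trees matches the conventional fidelity setting; screening runs use a
#' smaller ensemble via configuration.
#'
#' @param X data.frame of features.
#' @param y numeric response.
#' @param n_trees ensemble size.
#' @param mtry features sampled per split; default `max(1, floor(p/3))`,
#'   the regression-forest convention.
#' @param min_leaf minimum observations per leaf.
#' @param max_depth maximum depth per tree.
#' @param bootstrap draw bootstrap samples (TRUE) or fit every tree on the
#'   full data (FALSE).
#' @param seed integer seed; fixed seed gives identical forests.
#' @return an object of class `random_forest`.
#' @export
fit_random_forest <- function(X, y, n_trees = 500L, mtry = NULL,
                              min_leaf = 5L, max_depth = 25L,
                              bootstrap = TRUE, seed = 1L) {
  meta <- encode_features(X)
  y <- as.numeric(y)
  n <- length(y)
  if (n != nrow(meta$Xm)) stop("X and y lengths differ")
  if (n < 2L) stop("need at least 2 observations")
  p <- ncol(meta$Xm)
  if (is.null(mtry)) mtry <- max(1L, p %/% 3L)
  if (mtry > p) stop("mtry exceeds the number of features")
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    trees[[b]] <- grow_tree(meta$Xm[idx, , drop = FALSE], meta$is_cat,
                            y[idx], as.integer(min_leaf),
                            as.integer(max_depth), as.integer(mtry))
  }
  structure(list(trees = trees,
                 meta = meta[c("is_cat", "levels", "feature_names")],
                 n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                 max_depth = max_depth, bootstrap = bootstrap, seed = seed),
            class = "random_forest")
}

#' @export
print.random_forest <- function(x, ...) {
  cat(sprintf("<random_forest> %d trees, mtry=%d, min_leaf=%d, seed=%d\n",
              x$n_trees, x$mtry, x$min_leaf, x$seed))
  invisible(x)
}

forest_tree <- function(forest, b) {
  tr <- forest$trees[[b]]
  tr$meta <- forest$meta
  class(tr) <- "regression_tree"
  tr
}

#' Predict from a random forest
#'
#' @param object a `random_forest`.
#' @param newdata data.frame with every feature column.
#' @param ... unused.
#' @return mean of the member trees' predictions per row.
#' @export
predict.random_forest <- function(object, newdata, ...) {
  Xm <- encode_new_data(object$meta, newdata)
  pred <- numeric(nrow(Xm))
  for (b in seq_len(object$n_trees))
    pred <- pred + predict_encoded(forest_tree(object, b), Xm)
  pred / object$n_trees
}
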