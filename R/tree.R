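# Feature encoding shared by trees and forests: numeric columns pass
# through; factor/character columns become integer level codes with the
# sorted level table kept for prediction on new data.
encode_features <- function(X) {
  if (!is.data.frame(X)) X <- as.data.frame(X)
  if (nrow(X) == 0L) stop("empty feature data")
  p <- ncol(X)
  is_cat <- logical(p)
  levels_list <- vector("list", p)
  Xm <- matrix(0, nrow(X), p, dimnames = list(NULL, names(X)))
  for (j in seq_len(p)) {
    v <- X[[j]]
    if (is.factor(v) || is.character(v)) {
      lv <- sort(unique(as.character(v)))
      is_cat[j] <- TRUE
      levels_list[[j]] <- lv
      Xm[, j] <- match(as.character(v), lv)
    } else {
      Xm[, j] <- as.numeric(v)
    }
  }
  if (anyNA(Xm)) stop("features must not contain missing values")
  list(Xm = Xm, is_cat = is_cat, levels = levels_list,
       feature_names = names(X))
}

encode_new_data <- function(meta, newdata) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata)
  missing <- setdiff(meta$feature_names, names(newdata))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  p <- length(meta$feature_names)
  Xm <- matrix(0, nrow(newdata), p,
               dimnames = list(NULL, meta$feature_names))
  for (j in seq_len(p)) {
    v <- newdata[[meta$feature_names[j]]]
    if (meta$is_cat[j]) {
      # unseen categories get code NA and route right at every split
      Xm[, j] <- match(as.character(v), meta$levels[[j]])
    } else {
      Xm[, j] <- as.numeric(v)
      if (anyNA(Xm[, j])) stop("missing values in feature ",
                               meta$feature_names[j])
    }
  }
  Xm
}

best_numeric_split <- function(x, yv, min_leaf) {
  m <- length(x)
  o <- order(x)
  xs <- x[o]; ys <- yv[o]
  cl <- cumsum(ys); S <- cl[m]
  i <- seq_len(m - 1L)
  ok <- (i >= min_leaf) & ((m - i) >= min_leaf) & (xs[-1L] > xs[-m])
  if (!any(ok)) return(NULL)
  sc <- cl[i]^2 / i + (S - cl[i])^2 / (m - i)
  sc[!ok] <- -Inf
  b <- which.max(sc)
  list(score = sc[b], threshold = (xs[b] + xs[b + 1L]) / 2)
}

# CART-standard ordered-subset search: order the observed categories by mean
# response, then scan split points along that ordering.
best_categorical_split <- function(codes, yv, min_leaf) {
  s <- rowsum(yv, codes)
  cnt <- rowsum(rep(1, length(yv)), codes)
  G <- nrow(s)
  if (G < 2L) return(NULL)
  o <- order(s / cnt)
  cs <- cumsum(s[o]); cc <- cumsum(cnt[o])
  m <- cc[G]; S <- cs[G]
  k <- seq_len(G - 1L)
  ok <- (cc[k] >= min_leaf) & ((m - cc[k]) >= min_leaf)
  if (!any(ok)) return(NULL)
  sc <- cs[k]^2 / cc[k] + (S - cs[k])^2 / (m - cc[k])
  sc[!ok] <- -Inf
  b <- which.max(sc)
  list(score = sc[b],
       left_codes = as.numeric(rownames(s))[o][seq_len(b)])
}

grow_tree <- function(Xm, is_cat, y, min_leaf, max_depth, mtry) {
  n <- length(y); p <- ncol(Xm)
  max_nodes <- 2L * max(1L, n %/% max(1L, min_leaf)) + 1L
  feat <- rep(NA_integer_, max_nodes)
  thr <- rep(NA_real_, max_nodes)
  cats <- vector("list", max_nodes)
  left <- rep(NA_integer_, max_nodes)
  right <- rep(NA_integer_, max_nodes)
  val <- rep(NA_real_, max_nodes)
  nn <- integer(max_nodes)
  n_nodes <- 1L
  stack <- list(list(node = 1L, idx = seq_len(n), depth = 0L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    idx <- fr$idx
    yv <- y[idx]; m <- length(idx)
    val[fr$node] <- sum(yv) / m
    nn[fr$node] <- m
    if (fr$depth >= max_depth || m < 2L * min_leaf) next
    if (max(yv) - min(yv) < 1e-12) next  # zero-variance node
    cand <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    base_score <- sum(yv)^2 / m
    best <- NULL
    for (j in cand) {
      sp <- if (is_cat[j]) best_categorical_split(Xm[idx, j], yv, min_leaf)
            else best_numeric_split(Xm[idx, j], yv, min_leaf)
      if (!is.null(sp) && sp$score > base_score + 1e-10 &&
          (is.null(best) || sp$score > best$score)) {
        sp$j <- j
        best <- sp
      }
    }
    if (is.null(best)) next
    go_left <- if (is_cat[best$j]) Xm[idx, best$j] %in% best$left_codes
               else Xm[idx, best$j] <= best$threshold
    lid <- n_nodes + 1L; rid <- n_nodes + 2L
    n_nodes <- n_nodes + 2L
    feat[fr$node] <- best$j
    if (is_cat[best$j]) cats[[fr$node]] <- best$left_codes
    else thr[fr$node] <- best$threshold
    left[fr$node] <- lid; right[fr$node] <- rid
    stack[[length(stack) + 1L]] <- list(node = lid, idx = idx[go_left],
                                        depth = fr$depth + 1L)
    stack[[length(stack) + 1L]] <- list(node = rid, idx = idx[!go_left],
                                        depth = fr$depth + 1L)
  }
  keep <- seq_len(n_nodes)
  list(feature = feat[keep], threshold = thr[keep], cats = cats[keep],
       left = left[keep], right = right[keep], value = val[keep],
       n = nn[keep])
}

#' Fit a CART regression tree
#'
#' Greedy top-down growth: each split maximizes the reduction in the sum of
#' squared errors over candidate (feature, cut) pairs. Numeric features are
#' cut at midpoints between adjacent distinct observed values (ties at the
#' threshold go left); factor/character features are split by the standard
#' CART ordered-subset search over categories ranked by mean response.
#' Growth stops at `max_depth`, when a node is smaller than `2 * min_leaf`,
#' or when the node response has zero variance. Leaf predictions are the
#' training-response means of the observations routed there.
#'
#' @param X data.frame of features (numeric, factor or character columns).
#' @param y numeric response.
#' @param min_leaf minimum observations per leaf.
#' @param max_depth maximum tree depth (root is depth 0).
#' @param mtry number of features sampled per split; default all.
#' @return an object of class `regression_tree`.
#' @export
fit_regression_tree <- function(X, y, min_leaf = 5L, max_depth = 25L,
                                mtry = NULL) {
  meta <- encode_features(X)
  y <- as.numeric(y)
  if (length(y) != nrow(meta$Xm)) stop("X and y lengths differ")
  if (length(y) == 0L) stop("empty training data")
  p <- ncol(meta$Xm)
  if (is.null(mtry)) mtry <- p
  if (mtry > p) stop("mtry exceeds the number of features")
  if (mtry < 1L) stop("mtry must be >= 1")
  nodes <- grow_tree(meta$Xm, meta$is_cat, y, as.integer(min_leaf),
                     as.integer(max_depth), as.integer(mtry))
  structure(c(nodes, list(meta = meta[c("is_cat", "levels", "feature_names")],
                          min_leaf = min_leaf, max_depth = max_depth)),
            class = "regression_tree")
}

#' @export
print.regression_tree <- function(x, ...) {
  cat(sprintf("<regression_tree> %d nodes, %d leaves, %d training rows\n",
              length(x$value), sum(is.na(x$feature)), x$n[1L]))
  invisible(x)
}

predict_encoded <- function(tree, Xm) {
  pred <- numeric(nrow(Xm))
  if (nrow(Xm) == 0L) return(pred)
  stack <- list(list(node = 1L, idx = seq_len(nrow(Xm))))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node; idx <- fr$idx
    j <- tree$feature[node]
    if (is.na(j)) {
      pred[idx] <- tree$value[node]
    } else {
      xv <- Xm[idx, j]
      gl <- if (tree$meta$is_cat[j]) xv %in% tree$cats[[node]]
            else xv <= tree$threshold[node]
      if (any(gl))
        stack[[length(stack) + 1L]] <- list(node = tree$left[node],
                                            idx = idx[gl])
      if (!all(gl))
        stack[[length(stack) + 1L]] <- list(node = tree$right[node],
                                            idx = idx[!gl])
    }
  }
  pred
}

#' Predict from a regression tree
#'
#' Routes each row down the splits (values at a numeric threshold go left;
#' categories not in the recorded left subset, including categories unseen
#' in training, go right) and returns the leaf mean.
#'
#' @param tree a `regression_tree`.
#' @param newdata data.frame containing every feature column used to fit.
#' @return numeric vector of predictions.
#' @export
predict_tree <- function(tree, newdata) {
  stopifnot(inherits(tree, "regression_tree"))
  predict_encoded(tree, encode_new_data(tree$meta, newdata))
}

#' @export
predict.regression_tree <- function(object, newdata, ...) {
  predict_tree(object, newdata)
}
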