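test_that("tree growth stops correctly on degenerate and bounded cases", {
  X <- data.frame(x = runif(30))
  tr <- fit_regression_tree(X, rep(3.5, 30))
  expect_equal(length(tr$value), 1L)       # constant response: single leaf
  expect_equal(tr$value[1L], 3.5)

  set.seed(2)
  x <- c(runif(20, -2, -1), runif(20, 1, 2))
  y <- as.numeric(x > 0)
  tr2 <- fit_regression_tree(data.frame(x = x), y, min_leaf = 5)
  # exhaustive oracle: best SSE split over all midpoints
  xs <- sort(x)
  mids <- (xs[-1] + xs[-length(xs)]) / 2
  sse <- vapply(mids, function(t) {
    l <- y[x <= t]; r <- y[x > t]
    sum((l - mean(l))^2) + sum((r - mean(r))^2)
  }, numeric(1))
  best_mid <- mids[which.min(sse)]
  expect_equal(tr2$threshold[1L], best_mid)
  expect_true(tr2$threshold[1L] > -1 && tr2$threshold[1L] < 1)
  leaves <- sort(tr2$value[is.na(tr2$feature)])
  expect_equal(leaves[1], 0)
  expect_equal(leaves[length(leaves)], 1)

  tr3 <- fit_regression_tree(data.frame(x = x), y + rnorm(40, 0, 0.1),
                             min_leaf = 2, max_depth = 1)
  expect_lte(length(tr3$value), 3L)
  expect_error(fit_regression_tree(data.frame(x = numeric(0)), numeric(0)),
               "empty")
})

test_that("tree prediction routes rows like a recursive traversal", {
  X1 <- data.frame(x = runif(10))
  tr1 <- fit_regression_tree(X1, rep(10, 10))
  expect_equal(predict_tree(tr1, data.frame(x = c(-5, 0.5, 99))),
               rep(10, 3))

  # observed values sit at distinct points; threshold is their midpoint and
  # a query exactly at the threshold goes left
  tr2 <- fit_regression_tree(data.frame(x = rep(c(0, 1), each = 5)),
                             rep(c(0, 1), each = 5), min_leaf = 1)
  expect_equal(tr2$threshold[1L], 0.5)
  expect_equal(predict_tree(tr2, data.frame(x = 0.5)), 0)

  set.seed(3)
  n <- 300
  X <- data.frame(a = rnorm(n), b = runif(n),
                  f = sample(c("u", "v", "w"), n, TRUE))
  y <- X$a + 2 * (X$f == "u") + rnorm(n, 0, 0.3)
  tr <- fit_regression_tree(X, y, min_leaf = 10)
  new <- X[sample.int(n, 100), ]
  vec <- predict_tree(tr, new)
  ref <- vapply(seq_len(100), function(i) trace_tree_row(tr, new[i, ]),
                numeric(1))
  expect_equal(vec, ref)

  expect_error(predict_tree(tr, new[, c("a", "b")]), "missing feature")
})

test_that("a degenerate forest reduces to a single CART and forests average trees", {
  set.seed(4)
  n <- 200
  X <- data.frame(x = runif(n), z = runif(n))
  y <- sin(4 * X$x) + rnorm(n, 0.1)
  fo1 <- fit_random_forest(X, y, n_trees = 1, mtry = 2, bootstrap = FALSE,
                           min_leaf = 10, seed = 1)
  tr <- fit_regression_tree(X, y, min_leaf = 10)
  expect_equal(predict(fo1, X), predict_tree(tr, X))

  fo <- fit_random_forest(X, y, n_trees = 7, min_leaf = 10, seed = 2)
  per_tree <- vapply(seq_len(7), function(b) {
    predict_tree(pm25screen:::forest_tree(fo, b), X[1:5, ])
  }, numeric(5))
  expect_equal(predict(fo, X[1:5, ]), rowMeans(per_tree))

  fo_a <- fit_random_forest(X, y, n_trees = 10, seed = 99)
  fo_b <- fit_random_forest(X, y, n_trees = 10, seed = 99)
  expect_identical(predict(fo_a, X), predict(fo_b, X))

  expect_error(fit_random_forest(X, y, mtry = 5), "mtry")
})

test_that("partial dependence equals the brute-force Friedman average", {
  set.seed(5)
  n <- 150
  X <- data.frame(x = runif(n), w = runif(n))
  y <- as.numeric(X$x > 0.5) + 0.5 * as.numeric(X$w > 0.5)

  tr0 <- fit_regression_tree(X, rep(2, n))
  pd0 <- partial_dependence(tr0, X, "x", grid = c(0.2, 0.8))
  expect_equal(pd0$value, c(2, 2))  # constant model: flat curve

  tr1 <- fit_regression_tree(X, y, min_leaf = 20, max_depth = 1)
  grid <- seq(0.05, 0.95, by = 0.1)
  pd1 <- partial_dependence(tr1, X, "x", grid = grid)
  brute <- vapply(grid, function(g) {
    Z <- X; Z$x <- g
    mean(predict_tree(tr1, Z))
  }, numeric(1))
  expect_equal(pd1$value, brute, tolerance = 1e-12)
  # depth-1 tree on x only: step curve at the threshold
  thr <- tr1$threshold[1L]
  expect_equal(unique(pd1$value[grid <= thr]), tr1$value[tr1$left[1L]])
  expect_equal(unique(pd1$value[grid > thr]), tr1$value[tr1$right[1L]])

  set.seed(6)
  fo <- fit_random_forest(X, y, n_trees = 25, min_leaf = 15, seed = 3)
  gridf <- c(0.1, 0.5, 0.9)
  pdf_ <- partial_dependence(fo, X, "x", grid = gridf)
  brutef <- vapply(gridf, function(g) {
    Z <- X; Z$x <- g
    mean(predict(fo, Z))
  }, numeric(1))
  expect_equal(pdf_$value, brutef, tolerance = 1e-12)

  expect_error(partial_dependence(fo, X[0, ], "x"), "non-empty")
  expect_error(partial_dependence(fo, X, "nope"), "not a model input")
  expect_error(partial_dependence(fo, X, "x", grid = c(2, 1)),
               "strictly increasing")
})

test_that("PDP over observed values conserves the mean prediction", {
  # exact when the model has no interactions with the target feature, so
  # use a single-feature tree (PDP value at g is then the prediction at g)
  set.seed(7)
  n <- 120
  X <- data.frame(x = sample(seq(0, 1, 0.05), n, TRUE))
  y <- 3 * X$x + rnorm(n, 0, 0.2)
  tr <- fit_regression_tree(X, y, min_leaf = 8)
  pd <- partial_dependence(tr, X, "x")  # grid = observed unique values
  wts <- table(factor(X$x, levels = pd$grid))
  expect_equal(sum(pd$value * as.numeric(wts)) / n,
               mean(predict_tree(tr, X)), tolerance = 1e-10)
})

test_that("an additive linear signal is recovered by the forest PDP slope", {
  set.seed(3)
  n <- 3000
  X <- data.frame(x1 = runif(n), x2 = runif(n))
  y <- 2 * X$x1 + rnorm(n, 0, 0.2)
  fo <- fit_random_forest(X, y, n_trees = 100, mtry = 2, min_leaf = 5,
                          seed = 5)
  pd <- partial_dependence(fo, X, "x1")
  g <- pd$grid - mean(pd$grid)
  slope <- sum(g * pd$value) / sum(g^2)
  expect_lt(abs(slope - 2), 0.2)
})

test_that("PDP effect size summarizes curves as normalized slopes", {
  flat <- structure(data.frame(grid = 0:10, value = rep(4, 11)),
                    class = c("pdp_curve", "data.frame"))
  expect_equal(pdp_effect_size(flat), 0)

  grid <- seq(0, 50, by = 2)
  curve <- structure(data.frame(grid = grid, value = 10 * (1 + 1e-4 * grid)),
                     class = c("pdp_curve", "data.frame"))
  # closed form: slope 1e-3, baseline mean(value)
  expected <- 100 * (10 * 1e-4) * 10 / mean(curve$value)
  expect_equal(pdp_effect_size(curve, 10), expected, tolerance = 1e-6)
  expect_gt(pdp_effect_size(curve, 10), 0)   # increasing curve, positive sign

  zero <- structure(data.frame(grid = 0:3, value = c(-1, 1, -1, 1)),
                    class = c("pdp_curve", "data.frame"))
  expect_error(pdp_effect_size(zero), "baseline")
  expect_error(pdp_effect_size(flat[1, ]), "2 grid points")
})
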