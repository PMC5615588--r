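test_that("quantile discretization bins evenly and preserves categoricals", {
  pan <- data.frame(v = 1:100, month = rep(1:12, length.out = 100))
  dp <- discretize(pan, 4, vars = c("v", "month"))
  expect_equal(unname(dp$arity[["v"]]), 4L)
  expect_equal(as.vector(table(dp$values[, "v"])), rep(25L, 4))
  expect_equal(unname(dp$arity[["month"]]), 12L)
  expect_equal(dp$values[, "month"], rep(1:12, length.out = 100),
               ignore_attr = TRUE)
  expect_error(discretize(pan, 1), "n_bins")

  # heavily tied vectors: realized bins never exceed n_bins, none empty
  set.seed(14)
  for (k in 1:10) {
    tied <- data.frame(v = sample(1:3, 200, TRUE, prob = c(0.8, 0.1, 0.1)))
    dpt <- discretize(tied, 4, vars = "v")
    tab <- table(dpt$values[, "v"])
    expect_lte(length(tab), 4L)
    expect_true(all(tab > 0))
    expect_equal(sort(unique(as.integer(dpt$values[, "v"]))),
                 seq_len(dpt$arity[["v"]]))
  }

  expect_warning(discretize(data.frame(v = rep(2.5, 20)), 4, vars = "v"),
                 "constant")
})

test_that("G-squared statistic matches direct formula evaluation", {
  balanced <- toy_discrete(x = rep(1:2, each = 50),
                           y = rep(rep(1:2, 2), times = c(25, 25, 25, 25)))
  r0 <- ci_test_g2("x", "y", data = balanced)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  diag2 <- toy_discrete(x = rep(1:2, each = 50), y = rep(1:2, each = 50))
  rd <- ci_test_g2("x", "y", data = diag2)
  expect_equal(rd$statistic, 200 * log(2), tolerance = 1e-12)
  expect_equal(rd$dof, 1L)

  # dof bookkeeping with a conditioning variable and full margins
  set.seed(15)
  full <- toy_discrete(x = sample(1:3, 600, TRUE), y = sample(1:4, 600, TRUE),
                       z = sample(1:2, 600, TRUE))
  rf <- ci_test_g2("x", "y", "z", full)
  expect_equal(rf$dof, (3 - 1) * (4 - 1) * 2)

  expect_error(ci_test_g2("x", "x", data = diag2), "differ")
  expect_error(ci_test_g2("x", "y", "x", full), "not be in Z")
  expect_error(ci_test_g2("x", "q", data = diag2), "unknown")
})

test_that("G-squared test is calibrated under the null (small replicate check)", {
  set.seed(21)
  rej <- mean(replicate(150, {
    vals <- toy_discrete(x = sample(1:4, 4000, TRUE),
                         y = sample(1:4, 4000, TRUE),
                         z = sample(1:2, 4000, TRUE))
    ci_test_g2("x", "y", "z", vals)$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("PC-stable recovers toy skeletons and matches exhaustive CI search", {
  v1 <- toy_discrete(x = rep(1:2, 10))
  st1 <- learn_structure_pc(v1)
  expect_equal(sum(st1$amat), 0)

  set.seed(5)
  n <- 5000
  x <- sample(1:3, n, TRUE)
  y <- ifelse(runif(n) < 0.8, x, sample(1:3, n, TRUE))
  z <- ifelse(runif(n) < 0.8, y, sample(1:3, n, TRUE))
  dp <- toy_discrete(X = x, Y = y, Z = z)
  st <- learn_structure_pc(dp)
  adj <- adjacency_matrix(st)
  expect_equal(adj["X", "Y"], 1L)
  expect_equal(adj["Y", "Z"], 1L)
  expect_equal(adj["X", "Z"], 0L)

  # exhaustive oracle: an edge belongs to the skeleton iff no conditioning
  # subset of the remaining variables separates the pair
  vars <- dp$vars
  for (a in vars) for (b in vars) {
    if (a >= b) next
    others <- setdiff(vars, c(a, b))
    subsets <- c(list(character(0)), as.list(others), list(others))
    separated <- any(vapply(subsets, function(S) {
      ci_test_g2(a, b, S, dp)$p_value > 0.05
    }, logical(1)))
    expect_equal(adj[a, b] == 1L, !separated)
  }
})

test_that("PC returns empty skeletons on independent variables", {
  set.seed(16)
  empty_rate <- mean(vapply(1:10, function(s) {
    set.seed(s + 100)
    dp <- toy_discrete(a = sample(1:3, 2000, TRUE),
                       b = sample(1:3, 2000, TRUE),
                       c = sample(1:4, 2000, TRUE))
    sum(learn_structure_pc(dp)$amat) == 0
  }, logical(1)))
  expect_gte(empty_rate, 0.9)
})

test_that("hill climbing maximizes BIC and is seed-deterministic", {
  set.seed(17)
  dp_ind <- toy_discrete(a = sample(1:3, 2000, TRUE),
                         b = sample(1:3, 2000, TRUE))
  hc <- learn_structure_hc(dp_ind, restarts = 3, seed = 1)
  empty <- network_structure(dp_ind$vars)
  # direct oracle: empty graph beats every single-edge graph
  for (e in list(c("a", "b"), c("b", "a"))) {
    single <- network_structure(dp_ind$vars, rbind(e))
    expect_gte(bic_score(empty, dp_ind), bic_score(single, dp_ind))
  }
  expect_equal(sum(hc$amat), 0)

  set.seed(18)
  n <- 3000
  x <- sample(1:3, n, TRUE)
  y <- ifelse(runif(n) < 0.85, x, sample(1:3, n, TRUE))
  z <- ifelse(runif(n) < 0.85, y, sample(1:3, n, TRUE))
  dp <- toy_discrete(X = x, Y = y, Z = z)
  hc2 <- learn_structure_hc(dp, restarts = 3, seed = 2)
  expect_gte(hc2$score, bic_score(network_structure(dp$vars), dp))
  hc2b <- learn_structure_hc(dp, restarts = 3, seed = 2)
  expect_identical(hc2$amat, hc2b$amat)

  # strong-signal toys: PC and HC agree on the skeleton
  expect_identical(adjacency_matrix(hc2),
                   adjacency_matrix(learn_structure_pc(dp)))
})

test_that("BIC decomposes into hand-computable family scores", {
  dp <- toy_discrete(x = c(1, 1, 1, 2, 2, 2, 2, 2),
                     y = c(1, 1, 2, 1, 2, 2, 2, 2))
  n <- 8
  # empty graph: marginal multinomial log-likelihoods minus penalties
  ll_x <- 3 * log(3 / 8) + 5 * log(5 / 8)
  ll_y <- 3 * log(3 / 8) + 5 * log(5 / 8)
  expected <- (ll_x - log(n) / 2 * 1) + (ll_y - log(n) / 2 * 1)
  expect_equal(bic_score(network_structure(dp$vars), dp), expected,
               tolerance = 1e-12)

  # adding an edge never decreases the likelihood term
  with_edge <- network_structure(dp$vars, rbind(c("x", "y")))
  ll_term <- function(st) {
    penalty <- sum(vapply(seq_along(st$nodes), function(k) {
      npar <- prod(dp$arity[st$nodes[which(st$amat[, k] > 0)]])
      (dp$arity[[st$nodes[k]]] - 1) * max(1, npar)
    }, numeric(1))) * log(n) / 2
    bic_score(st, dp) + penalty
  }
  expect_gte(ll_term(with_edge) + 1e-12, ll_term(network_structure(dp$vars)))

  # score equivalence: x -> y and y -> x are the same multinomial model
  expect_equal(bic_score(with_edge, dp),
               bic_score(network_structure(dp$vars, rbind(c("y", "x"))), dp),
               tolerance = 1e-12)

  cyc <- network_structure(dp$vars)
  cyc$amat["x", "y"] <- 1L
  cyc$amat["y", "x"] <- 1L
  expect_error(bic_score(cyc, dp), "cycle")
})

test_that("adjacency queries and Markov blankets follow graph definitions", {
  chain <- network_structure(c("X", "Y", "Z"),
                             rbind(c("X", "Y"), c("Y", "Z")))
  expect_equal(markov_blanket(chain, "Y"), c("X", "Z"))
  expect_false(adjacency_query(chain, "X", "Z"))
  expect_true(adjacency_query(chain, "Y", "X"))

  collider <- network_structure(c("X", "Y", "Z"),
                                rbind(c("X", "Y"), c("Z", "Y")))
  expect_equal(markov_blanket(collider, "X"), c("Y", "Z"))

  empty <- network_structure(c("A", "B"))
  expect_equal(markov_blanket(empty, "A"), character(0))
  expect_error(markov_blanket(empty, "Q"), "unknown")
  expect_error(adjacency_query(empty, "A", "Q"), "unknown")
})
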