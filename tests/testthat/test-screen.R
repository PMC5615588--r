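test_that("panel summaries match order-statistics oracles", {
  pan <- data.frame(count_m75 = c(1, 2, 3, 4, 5))
  s <- summarize_panel(pan, "count_m75")
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(s$total, 15)

  s1 <- summarize_panel(data.frame(pm25 = 7.7), "pm25")
  expect_equal(s1$sd, 0)

  set.seed(19)
  x <- rnorm(501)
  s2 <- summarize_panel(data.frame(pm25 = x), "pm25")
  # sort-based interpolation oracle (type-7 definition written out)
  q_oracle <- function(x, p) {
    xs <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(x))] - xs[lo])
  }
  for (pp in c(0.10, 0.25, 0.50, 0.75, 0.90)) {
    got <- s2[[c("p10", "p25", "median", "p75", "p90")[
      match(pp, c(0.10, 0.25, 0.50, 0.75, 0.90))]]]
    expect_equal(got, q_oracle(x, pp), tolerance = 1e-12)
  }
  expect_error(summarize_panel(data.frame()), "non-empty")
})

test_that("Spearman matrix handles monotone pairs and ties", {
  pan <- data.frame(pm25 = 1:10, temp_avg = (1:10)^2,
                    dew_point = -(1:10)^3)
  r <- spearman_matrix(pan, c("pm25", "temp_avg", "dew_point"))
  expect_equal(r["pm25", "temp_avg"], 1)
  expect_equal(r["pm25", "dew_point"], -1)
  expect_equal(diag(r), c(pm25 = 1, temp_avg = 1, dew_point = 1))

  set.seed(20)
  tied <- data.frame(a = sample(1:4, 60, TRUE), b = sample(1:5, 60, TRUE))
  rt <- spearman_matrix(tied, c("a", "b"))
  oracle <- cor(rank(tied$a), rank(tied$b))  # rank-then-Pearson
  expect_equal(rt["a", "b"], oracle, tolerance = 1e-10)

  expect_warning(spearman_matrix(data.frame(a = rep(1, 5), b = 1:5),
                                 c("a", "b")), "constant")
  expect_error(spearman_matrix(data.frame(a = 1:2, b = 2:1), c("a", "b")),
               "3 rows")
})

test_that("information screen and confounding flag read the structure correctly", {
  nodes <- c("pm25", "month", "count_m75", "count_f75", "count_1875")
  fig3_like <- network_structure(nodes,
                                 rbind(c("month", "pm25"),
                                       c("month", "count_f75"),
                                       c("count_m75", "count_f75")))
  v <- information_screen(fig3_like, "pm25", c("count_m75", "count_f75"))
  expect_equal(unname(v), c("not_adjacent", "not_adjacent"))

  with_edge <- network_structure(nodes, rbind(c("pm25", "count_f75")))
  v2 <- information_screen(with_edge, "pm25", c("count_m75", "count_f75"))
  expect_equal(unname(v2["count_f75"]), "exposure_adjacent")
  expect_error(information_screen(with_edge, "pm25", "count_absent"),
               "unknown")

  cf <- confounding_flag(fig3_like, c("count_m75", "count_f75"),
                         "count_1875")
  expect_true(cf$flag)
  expect_equal(nrow(cf$edges), 1L)
  expect_equal(cf$edges$a[1], "count_m75")

  disconnected <- network_structure(nodes, rbind(c("month", "pm25")))
  expect_false(confounding_flag(disconnected,
                                c("count_m75", "count_f75"),
                                "count_1875")$flag)
  expect_error(confounding_flag(fig3_like, "count_m75", "count_m75"),
               "disjoint")
})

test_that("the confounding flag stays quiet when all drivers are observed", {
  flags <- vapply(1:10, function(s) {
    p <- generate_panel(scenario_config(seed = s, confounder_strength = 0))
    st <- learn_structure_pc(discretize(p))
    confounding_flag(st, c("count_m75", "count_f75"), "count_1875")$flag
  }, logical(1))
  expect_gte(mean(!flags), 0.7)
})

test_that("the screen runs end to end, deterministically, and validates first", {
  cfg <- scenario_config(seed = 31, n_days = 400)
  panel <- generate_panel(cfg)
  scfg <- screen_config(seed = 31, n_trees = 30, forest_min_leaf = 50)
  rep1 <- run_screen(panel, scfg)
  rep2 <- run_screen(panel, scfg)
  expect_identical(rep1, rep2)

  expect_named(rep1$verdicts)
  expect_true(all(rep1$verdicts %in% c("exposure_adjacent", "not_adjacent")))
  expect_true(is.logical(rep1$confounding_flag))
  expect_equal(sort(names(rep1$regressions)), c("count_f75", "count_m75"))
  for (o in names(rep1$regressions)) {
    r <- rep1$regressions[[o]]
    expect_equal(r$poisson$beta, r$quasipoisson$beta)
    expect_true(r$quasipoisson$se >= r$poisson$se)  # overdispersed counts
  }
  expect_true(all(c("pm25", "count_1875") %in% names(rep1$pdp$count_m75)))

  bad <- panel
  bad$count_m75[5] <- -1
  expect_error(run_screen(bad, scfg), "row 5")
})

test_that("screen reports round-trip through the report directory", {
  cfg <- scenario_config(seed = 32, n_days = 300)
  panel <- generate_panel(cfg)
  rep <- run_screen(panel, screen_config(seed = 32, n_trees = 20,
                                         forest_min_leaf = 50))
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir,
    c("report.json", "report.md", "structure.dot", "structure.graphml",
      "adjacency.csv")))))
  back <- read_report_json(dir)
  expect_equal(unlist(back$verdicts), unlist(rep$verdicts))
  expect_equal(back$confounding_flag, rep$confounding_flag)
  expect_equal(back$regressions$count_m75$quasipoisson$beta,
               rep$regressions$count_m75$quasipoisson$beta,
               tolerance = 1e-12)
  expect_equal(back$pdp$count_m75$pm25$effect_size_per_10,
               rep$pdp$count_m75$pm25$effect_size_per_10,
               tolerance = 1e-12)
  expect_equal(unlist(back$structure$nodes), rep$structure$nodes)
})
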