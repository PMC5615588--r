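# Small random panel with non-degenerate temperature columns, for
# regression-oracle tests.
random_small_panel <- function(n = 120, seed = 1) {
  set.seed(seed)
  pan <- data.frame(
    pm25 = exp(rnorm(n, 2.4, 0.4)),
    county = sample(c("dallas", "harris"), n, TRUE),
    year = sample(2003:2005, n, TRUE),
    month = sample(1:4, n, TRUE),
    temp_avg = rnorm(n, 69, 10))
  pan$temp_min <- pan$temp_avg - 10 + rnorm(n, 0, 2)
  pan$temp_max <- pan$temp_avg + 10 + rnorm(n, 0, 2)
  pan$dew_point <- pan$temp_avg - 13 + rnorm(n, 0, 4)
  pan$count_f75 <- rpois(n, 16)
  pan$count_m75 <- rpois(n, 10)
  pan
}

# Discrete panel built directly from integer code columns.
toy_discrete <- function(...) {
  cols <- list(...)
  vals <- do.call(cbind, lapply(cols, as.integer))
  colnames(vals) <- names(cols)
  structure(list(values = vals,
                 arity = vapply(cols, function(v) max(as.integer(v)),
                                integer(1)),
                 vars = names(cols), n = nrow(vals), info = list()),
            class = "discrete_panel")
}

# Reference recursive single-row tree traversal, independent of the
# vectorized prediction path.
trace_tree_row <- function(tree, row) {
  Xm <- pm25screen:::encode_new_data(tree$meta, row)
  node <- 1L
  repeat {
    j <- tree$feature[node]
    if (is.na(j)) return(tree$value[node])
    x <- Xm[1L, j]
    go_left <- if (tree$meta$is_cat[j]) x %in% tree$cats[[node]]
               else x <= tree$threshold[node]
    node <- if (go_left) tree$left[node] else tree$right[node]
  }
}

# Screen-style feature frame for forest fits.
screen_features <- function(panel, outcome) {
  controls <- setdiff(c("count_m75", "count_f75", "count_1875"), outcome)
  X <- panel[, c("county", "year", "month", "temp_avg", "temp_min",
                 "temp_max", "dew_point", "pm25", controls)]
  for (v in c("county", "year", "month")) X[[v]] <- factor(X[[v]])
  X
}
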