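#' Configuration of the full causal screen
#'
#' Bundles the tunables of every stage run by [run_screen()]. The forest
#' defaults to 100 trees for screening speed; set `n_trees = 500` for
#' fidelity runs matching the conventional ensemble size.
#'
#' @param seed integer seed used for the forest stage.
#' @param outcomes outcome count columns (75+ subpopulations).
#' @param exposure exposure column.
#' @param n_trees forest ensemble size.
#' @param forest_min_leaf,forest_max_depth,mtry forest growth parameters
#'   (`mtry = NULL` uses the p/3 convention). The default leaf size of 100
#'   keeps leaf means of Poisson counts stable (se below ~1/3 admission),
#'   which is the smoothness regime in which ensemble partial-dependence
#'   curves of daily admission counts are interpretable.
#' @param learner structure learner for the verdicts: `"pc"` (default) or
#'   `"hc"`.
#' @param alpha significance level of the PC conditional-independence tests.
#' @param n_bins quantile bins for discretization.
#' @param max_cond maximum PC conditioning-set size.
#' @param hc_restarts random restarts for the hill-climbing learner.
#' @param include_1875 include the pooled 18-75 count as a network node and
#'   forest control.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(seed = 1L,
                          outcomes = c("count_m75", "count_f75"),
                          exposure = "pm25",
                          n_trees = 100L,
                          forest_min_leaf = 100L,
                          forest_max_depth = 25L,
                          mtry = NULL,
                          learner = c("pc", "hc"),
                          alpha = 0.05,
                          n_bins = 4L,
                          max_cond = 3L,
                          hc_restarts = 10L,
                          include_1875 = TRUE) {
  structure(list(seed = as.integer(seed), outcomes = outcomes,
                 exposure = exposure, n_trees = as.integer(n_trees),
                 forest_min_leaf = as.integer(forest_min_leaf),
                 forest_max_depth = as.integer(forest_max_depth),
                 mtry = mtry, learner = match.arg(learner), alpha = alpha,
                 n_bins = as.integer(n_bins), max_cond = as.integer(max_cond),
                 hc_restarts = as.integer(hc_restarts),
                 include_1875 = include_1875),
            class = "screen_config")
}

#' Information-principle screen of exposure-outcome adjacency
#'
#' A necessary-condition test only: a variable can be a direct cause of an
#' outcome only if it remains informative about it given the other measured
#' variables, i.e. is adjacent to it in the learned network. The verdict is
#' `"exposure_adjacent"` when the exposure-outcome edge is present (in
#' either direction) and `"not_adjacent"` otherwise; it is never an
#' affirmative causal claim.
#'
#' @param structure a `network_structure`.
#' @param exposure exposure node name.
#' @param outcomes outcome node names.
#' @return named character vector of verdicts, one per outcome.
#' @export
information_screen <- function(structure, exposure, outcomes) {
  vapply(outcomes, function(o) {
    if (adjacency_query(structure, exposure, o)) "exposure_adjacent"
    else "not_adjacent"
  }, character(1))
}

#' Negative-control confounding flag
#'
#' Fires when any outcome node is adjacent to a disjoint-subpopulation
#' control node, or when the outcome nodes are adjacent to each other:
#' hospitalization counts in disjoint subpopulations cannot cause one
#' another, so residual adjacency among them signals shared unmeasured
#' confounders.
#'
#' @param structure a `network_structure`.
#' @param outcome_nodes outcome node names.
#' @param control_nodes control node names; must be disjoint from
#'   `outcome_nodes`.
#' @return list with `flag` (logical) and `edges` (data.frame of the
#'   triggering pairs, possibly empty).
#' @export
confounding_flag <- function(structure, outcome_nodes, control_nodes) {
  if (length(intersect(outcome_nodes, control_nodes)))
    stop("outcome and control node sets must be disjoint")
  pairs <- NULL
  if (length(outcome_nodes) > 1L) {
    cmb <- utils::combn(outcome_nodes, 2L)
    pairs <- data.frame(a = cmb[1L, ], b = cmb[2L, ])
  }
  if (length(control_nodes))
    pairs <- rbind(pairs, expand.grid(a = outcome_nodes, b = control_nodes,
                                      stringsAsFactors = FALSE))
  hit <- vapply(seq_len(NROW(pairs)), function(k) {
    adjacency_query(structure, pairs$a[k], pairs$b[k])
  }, logical(1))
  list(flag = any(hit),
       edges = if (any(hit)) pairs[hit, , drop = FALSE]
               else pairs[0, , drop = FALSE])
}

forest_features <- function(panel, outcome, cfg) {
  controls <- setdiff(count_columns(), outcome)
  if (!cfg$include_1875) controls <- setdiff(controls, "count_1875")
  feats <- c("county", "year", "month", "temp_avg", "temp_min", "temp_max",
             "dew_point", cfg$exposure, controls)
  X <- panel[, feats]
  for (v in c("county", "year", "month")) X[[v]] <- factor(X[[v]])
  X
}

tree_summary <- function(tree) {
  used <- tree$meta$feature_names[unique(stats::na.omit(tree$feature))]
  list(n_nodes = length(tree$value),
       n_leaves = sum(is.na(tree$feature)),
       root_feature = if (is.na(tree$feature[1L])) NA_character_
                      else tree$meta$feature_names[tree$feature[1L]],
       features_used = used)
}

regression_stage <- function(panel, outcome, exposure) {
  spec <- design_spec(outcome)
  dm <- build_design_matrix(panel, spec)
  fits <- list(linear = fit_linear(dm$X, dm$y),
               poisson = fit_poisson_irls(dm$X, dm$y),
               quasipoisson = fit_quasipoisson(dm$X, dm$y))
  lapply(fits, function(f) {
    b <- f$coefficients[[exposure]]
    se <- f$se[[exposure]]
    z <- b / se
    row <- list(beta = b, se = se,
                ci_low = b - 1.959964 * se, ci_high = b + 1.959964 * se,
                p_value = 2 * stats::pnorm(-abs(z)),
                dispersion = f$dispersion)
    if (f$family != "gaussian") {
      row$percent_increase <- percent_increase_per_10ug(b)
      row$percent_ci <- percent_increase_per_10ug(c(row$ci_low, row$ci_high))
    }
    row$fit <- f
    row
  })
}

#' Run the full causal screen on a panel
#'
#' Executes, in order: descriptive summaries; the Spearman correlation
#' matrix; linear, Poisson and quasi-Poisson regressions of each 75+
#' outcome on the exposure (with county/year/month, the four temperature
#' variables and the opposite-sex count as adjustments) plus the
#' percent-increase conversion; a random forest per outcome conditioned on
#' the same covariates and the disjoint-subpopulation controls, with
#' partial-dependence curves and effect sizes for the exposure and for the
#' 18-75 control count; quantile discretization and network structure
#' learning; a single CART per outcome; and the adjacency verdicts and
#' confounding flag. Deterministic given the panel and config.
#'
#' @param panel a validated county-day panel.
#' @param cfg a [screen_config()].
#' @return a list of class `screen_report`.
#' @export
run_screen <- function(panel, cfg = screen_config()) {
  validate_panel(panel)
  report <- list(config = unclass(cfg))
  report$summary <- summarize_panel(panel)
  report$spearman <- spearman_matrix(panel)

  report$regressions <- lapply(stats::setNames(cfg$outcomes, cfg$outcomes),
                               function(o) {
    st <- regression_stage(panel, o, cfg$exposure)
    lapply(st, function(row) { row$fit <- glm_fit_to_list(row$fit); row })
  })

  pdp_features <- c(cfg$exposure, if (cfg$include_1875) "count_1875")
  report$pdp <- list()
  report$trees <- list()
  for (o in cfg$outcomes) {
    X <- forest_features(panel, o, cfg)
    y <- panel[[o]]
    forest <- fit_random_forest(X, y, n_trees = cfg$n_trees,
                                mtry = cfg$mtry,
                                min_leaf = cfg$forest_min_leaf,
                                max_depth = cfg$forest_max_depth,
                                seed = cfg$seed)
    report$pdp[[o]] <- lapply(stats::setNames(pdp_features, pdp_features),
                              function(f) {
      curve <- partial_dependence(forest, panel, f)
      list(feature = f, grid = curve$grid, value = curve$value,
           baseline = attr(curve, "baseline"),
           effect_size_per_10 = pdp_effect_size(curve, 10))
    })
    tr <- fit_regression_tree(X, y, min_leaf = max(cfg$forest_min_leaf, 20L),
                              max_depth = 6L)
    report$trees[[o]] <- tree_summary(tr)
  }

  dp <- discretize(panel, n_bins = cfg$n_bins,
                   vars = intersect(bn_variables(cfg$include_1875),
                                    names(panel)))
  structure_fit <- if (cfg$learner == "pc")
    learn_structure_pc(dp, alpha = cfg$alpha, max_cond = cfg$max_cond)
  else learn_structure_hc(dp, restarts = cfg$hc_restarts, seed = cfg$seed)
  report$structure <- structure_fit

  report$verdicts <- information_screen(structure_fit, cfg$exposure,
                                        cfg$outcomes)
  controls <- setdiff(intersect(count_columns(), dp$vars), cfg$outcomes)
  conf <- confounding_flag(structure_fit, cfg$outcomes, controls)
  report$confounding_flag <- conf$flag
  report$confounding_edges <- conf$edges
  class(report) <- "screen_report"
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n  verdicts:\n")
  for (o in names(x$verdicts))
    cat(sprintf("    %s: %s\n", o, x$verdicts[[o]]))
  cat("  confounding flag:", x$confounding_flag, "\n")
  invisible(x)
}
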