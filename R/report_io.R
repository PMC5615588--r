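structure_to_list <- function(st) {
  ed <- which(st$amat > 0, arr.ind = TRUE)
  ed <- ed[order(ed[, 1L], ed[, 2L]), , drop = FALSE]
  list(nodes = st$nodes,
       edges = if (nrow(ed))
         data.frame(from = st$nodes[ed[, 1L]], to = st$nodes[ed[, 2L]])
       else data.frame(from = character(0), to = character(0)),
       method = st$method,
       score = if (is.na(st$score)) NULL else st$score)
}

report_to_list <- function(report) {
  x <- unclass(report)
  x$spearman <- list(columns = colnames(x$spearman),
                     values = unname(as.data.frame(x$spearman)))
  x$structure <- structure_to_list(x$structure)
  x$verdicts <- as.list(x$verdicts)
  x
}

#' Write a screen report to a directory
#'
#' Emits `report.json` (the full report, full numeric precision,
#' deterministic field order), `report.md` (human-readable summary),
#' `structure.dot` and `structure.graphml`, `adjacency.csv`, and one
#' `pdp_<outcome>_<feature>.csv` per partial-dependence curve.
#'
#' @param report a `screen_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  export_graph(report$structure, file.path(dir, "structure.dot"), "dot")
  export_graph(report$structure, file.path(dir, "structure.graphml"),
               "graphml")
  write_adjacency_csv(report$structure, file.path(dir, "adjacency.csv"))
  for (o in names(report$pdp)) for (f in names(report$pdp[[o]])) {
    cv <- report$pdp[[o]][[f]]
    utils::write.csv(data.frame(grid = signif(cv$grid, 6),
                                value = signif(cv$value, 6)),
                     file.path(dir, sprintf("pdp_%s_%s.csv", o, f)),
                     row.names = FALSE, quote = FALSE)
  }
  md <- c("# Causal screen report", "",
          "## Verdicts (information screen)", "",
          sprintf("- %s vs %s: **%s**", report$config$exposure,
                  names(report$verdicts), unlist(report$verdicts)),
          "",
          sprintf("Confounding flag (disjoint-count adjacency): **%s**",
                  report$confounding_flag),
          "", "## Exposure coefficients", "")
  for (o in names(report$regressions)) {
    qp <- report$regressions[[o]]$quasipoisson
    md <- c(md, sprintf(
      "- %s quasi-Poisson: beta = %.5g (%.5g, %.5g), %% increase per 10 = %.3g, p = %.3g",
      o, qp$beta, qp$ci_low, qp$ci_high, qp$percent_increase, qp$p_value))
  }
  md <- c(md, "", "## PDP effect sizes (% per 10 units)", "")
  for (o in names(report$pdp)) for (f in names(report$pdp[[o]]))
    md <- c(md, sprintf("- %s vs %s: %.4g", o, f,
                        report$pdp[[o]][[f]]$effect_size_per_10))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Reload a written screen report
#'
#' @param dir directory previously written by [write_report()].
#' @return the parsed `report.json` as a list.
#' @export
read_report_json <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}
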