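#' Descriptive summary of a county-day panel
#'
#' Per-variable n, mean, sd, min, 10th/25th/50th/75th/90th percentiles, max
#' and total, for every numeric analysis column — the descriptive table a
#' county-day admissions study reports.
#'
#' @param panel data.frame.
#' @param columns columns to summarize; defaults to all numeric analysis
#'   columns present.
#' @return data.frame, one row per variable.
#' @export
summarize_panel <- function(panel,
                            columns = intersect(c("count_1875", "count_m75",
                                                  "count_f75", "pm25",
                                                  "temp_avg", "temp_min",
                                                  "temp_max", "dew_point"),
                                                names(panel))) {
  if (!is.data.frame(panel) || nrow(panel) == 0L)
    stop("panel must be a non-empty data.frame")
  rows <- lapply(columns, function(v) {
    x <- as.numeric(panel[[v]])
    q <- stats::quantile(x, probs = c(0.10, 0.25, 0.50, 0.75, 0.90),
                         names = FALSE, type = 7)
    data.frame(variable = v, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               min = min(x), p10 = q[1L], p25 = q[2L], median = q[3L],
               p75 = q[4L], p90 = q[5L], max = max(x), total = sum(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation matrix
#'
#' Pairwise Spearman rank correlations with average-rank tie handling
#' (via [stats::cor()]); the diagonal is 1. A constant column yields `NA`
#' entries and a warning naming it.
#'
#' @param panel data.frame with at least 3 rows.
#' @param columns columns to correlate.
#' @return symmetric correlation matrix.
#' @export
spearman_matrix <- function(panel,
                            columns = intersect(c("pm25", "temp_avg",
                                                  "temp_min", "temp_max",
                                                  "dew_point"),
                                                names(panel))) {
  if (nrow(panel) < 3L) stop("need at least 3 rows")
  X <- as.matrix(panel[, columns, drop = FALSE])
  const <- apply(X, 2L, function(v) max(v) - min(v) == 0)
  if (any(const))
    warning("constant column(s), correlations undefined: ",
            paste(columns[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(X, method = "spearman"))
  diag(r) <- 1
  r
}
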