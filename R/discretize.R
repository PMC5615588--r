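#' Default variable set for network structure learning
#'
#' County, year and month as categorical nodes; PM2.5, the four temperature
#' variables, and the three subpopulation admission counts as
#' quantile-discretized continuous nodes.
#'
#' @param include_1875 include the pooled 18-75 admission count node.
#' @return character vector of panel column names.
#' @export
bn_variables <- function(include_1875 = TRUE) {
  v <- c("county", "year", "month", "pm25", "temp_avg", "temp_min",
         "temp_max", "dew_point", "count_m75", "count_f75")
  if (include_1875) v <- c(v, "count_1875")
  v
}

#' Discretize a panel for contingency-table analysis
#'
#' Continuous variables are cut at empirical quantiles into at most `n_bins`
#' non-empty bins (heavily tied data may realize fewer); categorical
#' variables pass through with their observed levels. A constant variable
#' collapses to a single bin and is flagged with a warning.
#'
#' @param panel data.frame.
#' @param n_bins target number of bins for continuous variables (>= 2).
#' @param vars columns to include; defaults to [bn_variables()].
#' @param categorical which of `vars` are categorical; factor/character
#'   columns are always treated as categorical.
#' @return an object of class `discrete_panel`: integer value matrix
#'   (codes 1..arity), per-variable arity, bin edges for continuous
#'   variables and level labels for categorical ones.
#' @export
discretize <- function(panel, n_bins = 4L,
                       vars = intersect(bn_variables(), names(panel)),
                       categorical = c("county", "year", "month")) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  missing <- setdiff(vars, names(panel))
  if (length(missing))
    stop("panel is missing column(s): ", paste(missing, collapse = ", "))
  n <- nrow(panel)
  p <- length(vars)
  values <- matrix(0L, n, p, dimnames = list(NULL, vars))
  arity <- integer(p)
  info <- vector("list", p)
  names(arity) <- names(info) <- vars
  for (v in vars) {
    x <- panel[[v]]
    if (v %in% categorical || is.factor(x) || is.character(x)) {
      if (is.numeric(x)) {       # integer-coded categorical: numeric order
        lv <- sort(unique(x))
        values[, v] <- match(x, lv)
      } else {
        lv <- sort(unique(as.character(x)))
        values[, v] <- match(as.character(x), lv)
      }
      arity[v] <- length(lv)
      info[[v]] <- list(type = "categorical", levels = as.character(lv))
    } else {
      x <- as.numeric(x)
      if (max(x) - min(x) < .Machine$double.eps * max(1, abs(max(x)))) {
        warning("variable '", v, "' is constant; single bin")
        values[, v] <- 1L
        arity[v] <- 1L
        info[[v]] <- list(type = "continuous", breaks = range(x))
        next
      }
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE, type = 7))
      codes <- as.integer(cut(x, breaks = br, include.lowest = TRUE))
      # drop bins emptied by ties so codes are contiguous and none empty
      used <- sort(unique(codes))
      values[, v] <- match(codes, used)
      arity[v] <- length(used)
      info[[v]] <- list(type = "continuous", breaks = br)
    }
  }
  structure(list(values = values, arity = arity, info = info, vars = vars,
                 n = n),
            class = "discrete_panel")
}

#' @export
print.discrete_panel <- function(x, ...) {
  cat(sprintf("<discrete_panel> %d rows, %d variables\n", x$n,
              length(x$vars)))
  print(x$arity)
  invisible(x)
}
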