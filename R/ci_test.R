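resolve_vars <- function(dp, v) {
  idx <- if (is.character(v)) match(v, dp$vars) else as.integer(v)
  if (anyNA(idx)) stop("unknown variable(s): ",
                       paste(v[is.na(idx)], collapse = ", "))
  idx
}

combine_codes <- function(dp, idx) {
  # mixed-radix code over the given columns, 1-based
  if (length(idx) == 0L) return(list(code = rep(1L, dp$n), arity = 1L))
  code <- dp$values[, idx[1L]]
  a <- dp$arity[idx[1L]]
  for (k in idx[-1L]) {
    code <- code + a * (dp$values[, k] - 1L)
    a <- a * dp$arity[k]
  }
  list(code = code, arity = a)
}

#' G-squared test of conditional independence
#'
#' Likelihood-ratio test of `x` independent of `y` given the variables in
#' `Z`, on a discretized panel. Within each stratum of `Z` the statistic
#' accumulates `2 * sum(O * log(O / E))` over non-empty cells, with expected
#' counts from the stratum margins. Degrees of freedom use the standard
#' sparse-table adjustment: each stratum contributes
#' `(non-empty rows - 1) * (non-empty columns - 1)`, so empty strata and
#' empty margins do not inflate the reference distribution.
#'
#' @param x,y variable names (or indices); must differ and not be in `Z`.
#' @param Z character vector of conditioning variables (possibly empty).
#' @param data a `discrete_panel`.
#' @return list of class `ci_test`: `x`, `y`, `Z`, `statistic`, `dof`,
#'   `p_value`.
#' @export
ci_test_g2 <- function(x, y, Z = character(0), data) {
  stopifnot(inherits(data, "discrete_panel"))
  xi <- resolve_vars(data, x)
  yi <- resolve_vars(data, y)
  zi <- resolve_vars(data, Z)
  if (xi == yi) stop("x and y must differ")
  if (xi %in% zi || yi %in% zi) stop("x and y must not be in Z")
  ax <- data$arity[xi]; ay <- data$arity[yi]
  zc <- combine_codes(data, zi)
  az <- zc$arity
  code <- data$values[, xi] + ax * (data$values[, yi] - 1L) +
    (ax * ay) * (zc$code - 1L)
  M <- matrix(tabulate(code, nbins = ax * ay * az), ax * ay, az)
  tot <- colSums(M)
  if (all(tot == 0)) stop("insufficient data: every stratum is empty")
  ri <- rep(seq_len(ax), times = ay)
  ci <- rep(seq_len(ay), each = ax)
  rowm <- rowsum(M, ri)                       # ax x az
  colm <- rowsum(M, ci)                       # ay x az
  E <- rowm[ri, , drop = FALSE] * colm[ci, , drop = FALSE]
  E <- sweep(E, 2L, pmax(tot, 1), "/")
  pos <- M > 0
  G2 <- 2 * sum(M[pos] * log(M[pos] / E[pos]))
  dof <- sum(pmax(0L, colSums(rowm > 0) - 1L) *
             pmax(0L, colSums(colm > 0) - 1L))
  p <- if (dof == 0) 1 else stats::pchisq(G2, dof, lower.tail = FALSE)
  structure(list(x = data$vars[xi], y = data$vars[yi], Z = data$vars[zi],
                 statistic = G2, dof = dof, p_value = p),
            class = "ci_test")
}

#' @export
print.ci_test <- function(x, ...) {
  cat(sprintf("G2(%s, %s | %s) = %.4g, dof = %d, p = %.4g\n", x$x, x$y,
              if (length(x$Z)) paste(x$Z, collapse = ",") else "{}",
              x$statistic, x$dof, x$p_value))
  invisible(x)
}
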