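#' Design specification for the parametric baselines
#'
#' Describes one regression of a 75+ admission count on same-day PM2.5 with
#' the standard adjustment set: county, year and month as reference-coded
#' categorical covariates; the four temperature variables as continuous
#' covariates; and the opposite-sex 75+ count as a disjoint-subpopulation
#' control covariate.
#'
#' @param response `"count_m75"` or `"count_f75"`.
#' @param exposure exposure column, default `"pm25"`.
#' @param categorical categorical covariate columns.
#' @param continuous continuous covariate columns.
#' @param control control covariate column; defaults to the opposite-sex
#'   75+ count of `response`.
#' @return a list of class `design_spec`.
#' @export
design_spec <- function(response = c("count_m75", "count_f75"),
                        exposure = "pm25",
                        categorical = c("county", "year", "month"),
                        continuous = c("temp_avg", "temp_min", "temp_max",
                                       "dew_point"),
                        control = NULL) {
  response <- match.arg(response)
  if (is.null(control))
    control <- if (response == "count_m75") "count_f75" else "count_m75"
  if (identical(control, response))
    stop("response and control must be disjoint columns")
  structure(list(response = response, exposure = exposure,
                 categorical = categorical, continuous = continuous,
                 control = control),
            class = "design_spec")
}

#' Build the design matrix and response vector for a regression
#'
#' Expands each categorical covariate into (levels - 1) indicator columns
#' with the first sorted level as the reference; continuous covariates, the
#' exposure and the control count pass through unscaled. A categorical with
#' a single observed level contributes no columns.
#'
#' @param panel a validated panel data.frame.
#' @param spec a [design_spec()].
#' @return list with `X` (numeric matrix, first column the intercept) and
#'   `y` (response vector).
#' @export
build_design_matrix <- function(panel, spec) {
  if (!is.data.frame(panel) || nrow(panel) == 0L) stop("panel must be non-empty")
  needed <- c(spec$response, spec$exposure, spec$categorical, spec$continuous,
              spec$control)
  missing <- setdiff(needed, names(panel))
  if (length(missing))
    stop("panel is missing column(s): ", paste(missing, collapse = ", "))
  n <- nrow(panel)
  cols <- list()
  cols[["(Intercept)"]] <- rep(1, n)
  cols[[spec$exposure]] <- as.numeric(panel[[spec$exposure]])
  for (v in spec$categorical) {
    lv <- sort(unique(as.character(panel[[v]])))
    if (length(lv) < 2L) next  # degenerate level: contributes no columns
    for (l in lv[-1L])
      cols[[paste0(v, l)]] <- as.numeric(as.character(panel[[v]]) == l)
  }
  for (v in c(spec$continuous, spec$control))
    cols[[v]] <- as.numeric(panel[[v]])
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, y = as.numeric(panel[[spec$response]]))
}

new_glm_fit <- function(family, beta, se, dispersion, n_obs, fitted,
                        converged = TRUE, iterations = 0L) {
  structure(list(family = family, coefficients = beta, se = se,
                 dispersion = dispersion, n_obs = n_obs, fitted = fitted,
                 converged = converged, iterations = iterations),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> family=%s n=%d dispersion=%.4g converged=%s\n",
              x$family, x$n_obs, x$dispersion, x$converged))
  print(data.frame(estimate = x$coefficients, se = x$se,
                   z = x$coefficients / x$se))
  invisible(x)
}

#' Ordinary least squares fit
#'
#' Gaussian baseline fitted by QR-decomposed least squares; standard errors
#' come from the unbiased residual variance. A rank-deficient design is an
#' error rather than a silent drop.
#'
#' @param X design matrix (including the intercept column).
#' @param y response vector.
#' @return a `glm_fit` with `family = "gaussian"`; `dispersion` is the
#'   residual variance.
#' @export
fit_linear <- function(X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < p) stop("design matrix is rank deficient (singular fit)")
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  sigma2 <- if (n > p) rss / (n - p) else 0
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  names(se) <- names(beta) <- colnames(X)
  new_glm_fit("gaussian", beta, se, sigma2, n, fitted)
}

#' Poisson regression by iteratively reweighted least squares
#'
#' Log-link Poisson maximum likelihood. Each IRLS step solves a weighted
#' least-squares problem with weights equal to the current mean; convergence
#' is declared when the largest absolute coefficient change falls below
#' `tol`. Standard errors are Fisher-information based. Non-convergence is
#' flagged on the returned fit rather than raised.
#'
#' @param X design matrix.
#' @param y non-negative integer response.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the coefficient change.
#' @return a `glm_fit` with `family = "poisson"` and `dispersion = 1`.
#' @export
fit_poisson_irls <- function(X, y, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (any(y < 0) || any(y != floor(y))) stop("y must be non-negative integers")
  if (all(y == 0)) stop("all-zero response: Poisson MLE is degenerate")
  n <- nrow(X); p <- ncol(X)
  mu <- (y + mean(y)) / 2
  eta <- log(mu)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- mu
    z <- eta + (y - mu) / mu
    sw <- sqrt(w)
    qrx <- qr(X * sw)
    if (qrx$rank < p) stop("design matrix is rank deficient (singular fit)")
    beta_new <- qr.coef(qrx, z * sw)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    if (delta < tol) { converged <- TRUE; break }
  }
  xtwx_inv <- chol2inv(qr.R(qr(X * sqrt(mu))))
  se <- sqrt(pmax(diag(xtwx_inv), 0))
  names(se) <- names(beta) <- colnames(X)
  new_glm_fit("poisson", beta, se, 1, n, mu, converged, iter)
}

#' Quasi-Poisson regression
#'
#' Coefficients are the Poisson maximum-likelihood estimates; the dispersion
#' is the Pearson chi-square divided by the residual degrees of freedom, and
#' standard errors are the Poisson ones inflated by its square root. This is
#' the usual accommodation of overdispersed daily admission counts.
#'
#' @inheritParams fit_poisson_irls
#' @return a `glm_fit` with `family = "quasipoisson"`.
#' @export
fit_quasipoisson <- function(X, y, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("quasi-Poisson dispersion needs n > p")
  fit <- fit_poisson_irls(X, y, max_iter, tol)
  pearson <- sum((y - fit$fitted)^2 / fit$fitted)
  dispersion <- pearson / (n - p)
  fit$family <- "quasipoisson"
  fit$dispersion <- dispersion
  fit$se <- fit$se * sqrt(dispersion)
  fit
}

#' Percent increase in admissions per 10 ug/m3 of PM2.5
#'
#' Converts a log-rate coefficient per ug/m3 to the conventionally reported
#' percent increase per 10 ug/m3 increment:
#' `(exp(10 * beta) - 1) * 100`. Strictly increasing in `beta`, with inverse
#' `log(1 + pct/100) / 10`.
#'
#' @param beta log-rate coefficient(s) per ug/m3.
#' @return percent increase(s) per 10 ug/m3.
#' @export
percent_increase_per_10ug <- function(beta) {
  if (any(!is.finite(beta))) stop("beta must be finite")
  (exp(10 * beta) - 1) * 100
}

#' Serialize a fitted regression to a plain list (for JSON reports)
#'
#' @param fit a `glm_fit`.
#' @return list of family, coefficients, standard errors, dispersion, n.
#' @export
glm_fit_to_list <- function(fit) {
  list(family = fit$family,
       coefficients = as.list(fit$coefficients),
       se = as.list(fit$se),
       dispersion = fit$dispersion,
       n_obs = fit$n_obs,
       converged = fit$converged)
}
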