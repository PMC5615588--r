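#' Deterministic seasonal temperature curve
#'
#' Annual cosine cycle of daily average temperature:
#' `mean + amplitude * cos(2*pi*(day - phase)/365.25)`. No noise; the
#' stochastic panel generator adds day-to-day noise on top of this curve.
#'
#' @param day_of_year integer day(s) of year, 1..366.
#' @param mean annual mean temperature (F).
#' @param amplitude seasonal amplitude (F, >= 0).
#' @param phase day of year at which the curve peaks.
#' @return numeric vector of temperatures (F).
#' @export
seasonal_temperature <- function(day_of_year, mean, amplitude, phase = 199) {
  if (any(is.na(day_of_year)) || any(day_of_year < 1) || any(day_of_year > 366))
    stop("day_of_year must lie in 1..366")
  mean + amplitude * cos(2 * pi * (day_of_year - phase) / 365.25)
}

#' Shared latent confounder series
#'
#' Stationary AR(1) series on the count log-rate scale with marginal sd
#' `strength` and lag-1 autocorrelation `autocorr`. The same realized series
#' is added to the log-rate of every subpopulation count (and optionally to
#' log-PM2.5), so it acts as an unmeasured common cause across disjoint
#' subpopulations. `strength = 0` returns an all-zero series.
#'
#' @param n_days series length (>= 1).
#' @param strength marginal standard deviation (>= 0).
#' @param autocorr lag-1 autocorrelation, in [0, 1).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (as inside [generate_panel()]).
#' @return numeric vector of length `n_days`.
#' @export
latent_confounder_series <- function(n_days, strength, autocorr, seed = NULL) {
  if (n_days < 1) stop("n_days must be >= 1")
  if (strength < 0) stop("strength must be >= 0")
  if (autocorr < 0 || autocorr >= 1) stop("autocorr must lie in [0, 1)")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
  }
  if (strength == 0) return(numeric(n_days))
  e <- stats::rnorm(n_days)
  # unit-variance AR(1): x1 = e1, x_t = rho*x_{t-1} + sqrt(1-rho^2)*e_t
  innov <- c(e[1L], sqrt(1 - autocorr^2) * e[-1L])
  u <- as.numeric(stats::filter(innov, autocorr, method = "recursive"))
  strength * u
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Generate a synthetic county-day admissions panel
#'
#' Draws one record per county per day under the causal structure encoded in
#' the config: calendar -> temperature -> PM2.5, and
#' (month, temperature, county, latent confounder, PM2.5) -> Poisson
#' admission counts. All three subpopulation counts share the same latent
#' confounder realization on a given day. PM2.5 is log-normal (hence always
#' positive); minimum/maximum/dew-point temperatures are derived from the
#' daily average by fixed offsets plus noise, clamped to satisfy
#' `temp_min <= temp_avg <= temp_max` and `dew_point <= temp_max`.
#'
#' A fixed seed yields an identical panel.
#'
#' @param cfg a [scenario_config()].
#' @return a `data.frame` with columns `county, date, year, month, day,
#'   pm25, temp_avg, temp_min, temp_max, dew_point, count_m75, count_f75,
#'   count_1875`; `attr(, "confounder")` holds the latent series used.
#' @export
generate_panel <- function(cfg) {
  validate_scenario_config(cfg)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(cfg$seed)

  dates <- cfg$start_date + 0:(cfg$n_days - 1L)
  doy <- as.integer(format(dates, "%j"))
  month <- as.integer(format(dates, "%m"))
  year <- as.integer(format(dates, "%Y"))
  mday <- as.integer(format(dates, "%d"))
  temp_ref <- scenario_temp_ref(cfg)

  u <- latent_confounder_series(cfg$n_days, cfg$confounder_strength,
                                cfg$confounder_autocorr)

  per_county <- lapply(cfg$counties, function(cty) {
    n <- cfg$n_days
    temp_avg <- seasonal_temperature(doy, cfg$temp_mean_by_county[[cty]],
                                     cfg$temp_seasonal_amplitude,
                                     cfg$temp_phase_day) +
      stats::rnorm(n, 0, cfg$temp_noise_sd)
    temp_min <- pmin(temp_avg, temp_avg - 10.2 + stats::rnorm(n, 0, 2.5))
    temp_max <- pmax(temp_avg, temp_avg + 9.7 + stats::rnorm(n, 0, 2.5))
    dew_point <- pmin(temp_max, temp_avg - 13.5 + stats::rnorm(n, 0, 5))

    log_pm <- log(cfg$pm25_base) + cfg$pm25_month_effect[month] +
      cfg$pm25_temp_coeff * (temp_avg - temp_ref) +
      cfg$confounder_pm_coeff * u +
      stats::rnorm(n, 0, cfg$pm25_noise_sd)
    pm25 <- exp(log_pm)

    shared <- cfg$month_rate_effect[month] +
      cfg$temp_rate_coeff * (temp_avg - temp_ref) +
      cfg$county_rate_effect[[cty]] + u + cfg$beta_pm_true * pm25
    counts <- vapply(c("count_m75", "count_f75", "count_1875"), function(s) {
      stats::rpois(n, exp(log(cfg$baseline_rate[[s]]) + shared))
    }, integer(cfg$n_days))

    data.frame(county = cty, date = dates, year = year, month = month,
               day = mday, pm25 = pm25, temp_avg = temp_avg,
               temp_min = temp_min, temp_max = temp_max,
               dew_point = dew_point,
               count_m75 = counts[, 1L], count_f75 = counts[, 2L],
               count_1875 = counts[, 3L],
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, per_county)
  rownames(panel) <- NULL
  attr(panel, "confounder") <- u
  panel
}
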