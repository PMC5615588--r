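#' County-day panel schema
#'
#' Column names and semantic constraints every panel must satisfy before any
#' analysis stage runs: the fixed header, positive PM2.5, non-negative
#' integer admission counts, the temperature ordering
#' `temp_min <= temp_avg <= temp_max`, dew point not above the maximum
#' temperature, and month consistent with the date.
#'
#' @return character vector of required column names, in canonical order.
#' @export
panel_columns <- function() {
  c("county", "date", "year", "month", "day", "pm25", "temp_avg",
    "temp_min", "temp_max", "dew_point", "count_m75", "count_f75",
    "count_1875")
}

count_columns <- function() c("count_m75", "count_f75", "count_1875")

#' Validate a county-day panel against the schema
#'
#' @param panel a data.frame.
#' @return the panel, invisibly; errors name the offending column and the
#'   first offending row.
#' @export
validate_panel <- function(panel) {
  if (!is.data.frame(panel) || nrow(panel) == 0L)
    stop("panel must be a non-empty data.frame")
  missing <- setdiff(panel_columns(), names(panel))
  if (length(missing))
    stop("panel is missing required column(s): ", paste(missing, collapse = ", "))
  bad_row <- function(ok, what) {
    if (!all(ok)) stop(sprintf("panel validation failed: %s at row %d",
                               what, which(!ok)[1L]))
  }
  for (cc in count_columns()) {
    v <- panel[[cc]]
    bad_row(is.finite(v) & v >= 0 & v == floor(v),
            paste(cc, "must be a non-negative integer"))
  }
  bad_row(is.finite(panel$pm25) & panel$pm25 > 0, "pm25 must be > 0")
  bad_row(panel$temp_min <= panel$temp_avg + 1e-9, "temp_min > temp_avg")
  bad_row(panel$temp_avg <= panel$temp_max + 1e-9, "temp_avg > temp_max")
  bad_row(panel$dew_point <= panel$temp_max + 1e-9, "dew_point > temp_max")
  mo <- as.integer(format(as.Date(panel$date), "%m"))
  bad_row(panel$month == mo, "month inconsistent with date")
  invisible(panel)
}

#' Read and write panels as CSV
#'
#' The on-disk format is a comma-separated UTF-8 file with the fixed header
#' `county,date,year,month,day,pm25,temp_avg,temp_min,temp_max,dew_point,
#' count_m75,count_f75,count_1875`; dates are ISO-8601 and numerics are
#' unquoted. `read_panel_csv` validates after typing, so malformed or
#' unit-violating rows fail with the row number.
#'
#' @param panel a validated panel data.frame.
#' @param path CSV file path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns a validated panel.
#' @export
write_panel_csv <- function(panel, path) {
  validate_panel(panel)
  out <- panel[, panel_columns()]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(panel_columns(), names(panel))
  if (length(missing))
    stop("header is missing required column(s): ",
         paste(missing, collapse = ", "))
  panel$date <- as.Date(panel$date)
  if (anyNA(panel$date))
    stop("unparseable date at row ", which(is.na(panel$date))[1L])
  for (cc in c("year", "month", "day", count_columns()))
    panel[[cc]] <- as.integer(panel[[cc]])
  validate_panel(panel)
  panel
}
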