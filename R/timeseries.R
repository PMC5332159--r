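#' Construct a uniformly sampled time-series tibble
#'
#' The universal signal carrier of the package: a two-column tibble with
#' `time_s` (seconds, uniformly spaced) and `value`. The sampling rate and
#' unit are stored as attributes and survive the dplyr verbs used internally.
#'
#' @param time_s Numeric vector of sample times in seconds, strictly
#'   increasing and uniformly spaced.
#' @param value Numeric vector, same length as `time_s`.
#' @param units Character scalar naming the physical unit of `value`
#'   (e.g. `"mV"`, `"nA"`, `"au"`).
#' @param rate_hz Sampling rate. Defaults to the reciprocal median time step.
#'
#' @return A tibble of class `spasm_ts` with columns `time_s` and `value`.
#' @export
#' @examples
#' ts <- ts_tbl(seq(0, 1, by = 1e-3), rnorm(1001), units = "mV")
#' ts_rate(ts)
ts_tbl <- function(time_s, value, units = "au", rate_hz = NULL) {
  if (length(time_s) != length(value)) {
    abort("`time_s` and `value` must have the same length.", class = "spasm_error_input")
  }
  if (length(time_s) == 0) {
    abort("Empty time series.", class = "spasm_error_input")
  }
  if (anyNA(time_s) || anyNA(value)) {
    abort("Time series contains NA values.", class = "spasm_error_input")
  }
  if (is.unsorted(time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing.", class = "spasm_error_input")
  }
  if (is.null(rate_hz)) {
    rate_hz <- if (length(time_s) > 1) 1 / median(diff(time_s)) else NA_real_
  }
  out <- tibble::tibble(time_s = as.numeric(time_s), value = as.numeric(value))
  attr(out, "rate_hz") <- rate_hz
  attr(out, "units") <- units
  class(out) <- c("spasm_ts", class(out))
  out
}

#' @rdname ts_tbl
#' @param ts A `spasm_ts` tibble (or any tibble with a `time_s` column).
#' @export
ts_rate <- function(ts) {
  r <- attr(ts, "rate_hz")
  if (!is.null(r) && is.finite(r)) return(r)
  1 / median(diff(ts$time_s))
}

#' @rdname ts_tbl
#' @export
ts_units <- function(ts) attr(ts, "units") %||% "au"

ts_duration <- function(ts) ts$time_s[nrow(ts)] - ts$time_s[1]

#' Read a time series from a two-column CSV file
#'
#' Expects a header row and columns `time_s,value` (extra columns are kept).
#' Validates monotone time, absence of NA and, when `expected_rate` is given,
#' that the observed sampling rate matches within 1% jitter.
#'
#' @param path Path to the CSV file.
#' @param expected_rate Optional sampling rate in Hz to validate against.
#' @param units Unit label attached to the result.
#' @return A `spasm_ts` tibble.
#' @export
read_timeseries <- function(path, expected_rate = NULL, units = "au") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("time_s", "value") %in% names(df))) {
    abort("CSV must have columns `time_s` and `value`.", class = "spasm_error_format")
  }
  if (anyNA(df$time_s) || anyNA(df$value)) {
    abort("CSV contains NA values.", class = "spasm_error_format")
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing; rows appear shuffled.",
          class = "spasm_error_format")
  }
  dt <- diff(df$time_s)
  if (length(dt) > 1 && (max(dt) - min(dt)) > 0.01 * median(dt)) {
    abort("Sampling is not uniform within 1% jitter.", class = "spasm_error_format")
  }
  observed <- if (length(dt)) 1 / median(dt) else NA_real_
  if (!is.null(expected_rate) && is.finite(observed) &&
      abs(observed - expected_rate) > 0.01 * expected_rate) {
    abort(
      sprintf("Declared rate %g Hz but observed %g Hz.", expected_rate, observed),
      class = "spasm_error_format"
    )
  }
  ts_tbl(df$time_s, df$value, units = units, rate_hz = observed)
}

#' Write a time series to CSV
#'
#' @param ts A `spasm_ts` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.csv(ts[, c("time_s", "value")], path, row.names = FALSE)
  invisible(path)
}

#' Crop a time series to a window
#'
#' @param ts A `spasm_ts` tibble.
#' @param t0,t1 Window bounds in seconds (inclusive).
#' @return The cropped `spasm_ts`.
#' @export
ts_window <- function(ts, t0, t1) {
  if (t1 <= t0) abort("`t1` must exceed `t0`.", class = "spasm_error_input")
  if (t0 < ts$time_s[1] - 1e-9 || t1 > ts$time_s[nrow(ts)] + 1e-9) {
    abort("Window [t0, t1] lies outside the recording.", class = "spasm_error_input")
  }
  keep <- ts$time_s >= t0 - 1e-12 & ts$time_s <= t1 + 1e-12
  out <- ts[keep, ]
  attr(out, "rate_hz") <- attr(ts, "rate_hz")
  attr(out, "units") <- attr(ts, "units")
  class(out) <- class(ts)
  out
}
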