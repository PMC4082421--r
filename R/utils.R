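#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; agreement percentages and kappa
#' values here are reported with the conventional half-away-from-zero rule
#' (so 86.5 -> 87, -0.5 -> -1).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(c(86.747, 0.5, -0.5))
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Signed whole-minute difference a - b. Inputs live on a minute grid, so the
## round() only absorbs floating-point noise.
minute_diff <- function(a, b) {
  as.integer(round(as.numeric(difftime(a, b, units = "mins"))))
}

vz_time <- function(x) {
  as.POSIXct(x, tz = "UTC")
}

na_time <- function(n = 1L) {
  .POSIXct(rep(NA_real_, n), tz = "UTC")
}

## Minutes -> seconds, for POSIXct arithmetic.
mins <- function(x) {
  x * 60
}

vz_abort <- function(msg, class = "ventzero_error", ...) {
  rlang::abort(msg, class = c(class, "ventzero_error"), ...)
}

fmt_time <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M", tz = "UTC")
  out[is.na(x)] <- ""
  out
}

## Strict minute-grid timestamp parser. Accepts YYYY-MM-DDTHH:MM (optionally
## a space separator or an explicit :00 seconds field); anything else,
## including non-zero seconds, is rejected. Returns the parsed times plus the
## indices that failed so callers can report file line numbers.
parse_minute_times <- function(x) {
  x <- as.character(x)
  blank <- is.na(x) | x == ""
  pat <- "^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}(:00)?$"
  shaped <- !blank & grepl(pat, x)
  out <- na_time(length(x))
  if (any(shaped)) {
    parsed <- as.POSIXct(sub("T", " ", x[shaped]),
                         format = "%Y-%m-%d %H:%M", tz = "UTC")
    out[shaped] <- parsed
  }
  bad <- which(!blank & (!shaped | is.na(out)))
  list(times = out, bad = bad)
}

parse_logical_field <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1")] <- TRUE
  out[x %in% c("false", "f", "0")] <- FALSE
  bad <- which(!(x %in% c("true", "t", "1", "false", "f", "0")))
  list(values = out, bad = bad)
}
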