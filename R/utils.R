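# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

# Parse naive ISO-8601 local timestamps (no timezone). Stored as POSIXct in
# UTC purely as an unambiguous carrier of wall-clock time.
parse_ts <- function(x) {
  out <- as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop("unparseable timestamp(s), expected YYYY-MM-DDTHH:MM:SS: ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  }
  out
}

format_ts <- function(x) format(x, TS_FORMAT, tz = "UTC")

# Floor a POSIXct to the start of its clock minute.
floor_minute <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

# round() in R rounds halves to even; display values follow the
# half-away-from-zero convention (3685/30 -> 123).
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
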