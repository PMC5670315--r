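#' Participant registry
#'
#' Build and validate a participant table. Ages must lie in \[18, 120\] years
#' (the validated cohort design targets adults aged 18--65; the upper guard
#' merely rejects corrupt input) and identifiers must be unique.
#'
#' @param participant_id character vector of unique identifiers.
#' @param age_years numeric vector of ages in years; fractional ages are
#'   accepted and never rounded.
#' @param label optional display letters ("A".."J" style); `NA` allowed.
#' @return A `data.frame` with columns `participant_id`, `age_years`, `label`.
#' @examples
#' participants(c("P01", "P02"), c(24, 31))
#' @export
participants <- function(participant_id, age_years, label = NA_character_) {
  df <- data.frame(participant_id = as.character(participant_id),
                   age_years = as.numeric(age_years),
                   label = rep_len(as.character(label), length(participant_id)),
                   stringsAsFactors = FALSE)
  validate_participants(df)
  df
}

validate_participants <- function(df) {
  req <- c("participant_id", "age_years")
  if (!all(req %in% names(df))) {
    stopf("participant table must have columns %s", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$participant_id)) {
    stopf("duplicate participant_id: %s",
          paste(unique(df$participant_id[duplicated(df$participant_id)]), collapse = ", "))
  }
  bad <- !is.finite(df$age_years) | df$age_years < 18 | df$age_years > 120
  if (any(bad)) {
    stopf("age_years out of range [18, 120] for: %s",
          paste(df$participant_id[bad], collapse = ", "))
  }
  invisible(df)
}

#' Read a participant metadata CSV
#'
#' Expects header `participant_id,age_years` with an optional `label` column.
#'
#' @param path file path.
#' @return A participant `data.frame` (see [participants()]).
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  ok <- identical(names(df), c("participant_id", "age_years")) ||
    identical(names(df), c("participant_id", "age_years", "label"))
  if (!ok) {
    stopf("bad participant CSV header in %s: expected participant_id,age_years[,label]", path)
  }
  if (is.null(df$label)) df$label <- NA_character_
  participants(df$participant_id, suppressWarnings(as.numeric(df$age_years)), df$label)
}

#' Construct a heart-rate sensor stream
#'
#' A stream holds timestamped integer heart-rate samples from one device worn
#' by one participant. `hr_bpm = 0` is the no-valid-reading (nonwear) sentinel;
#' valid readings lie in \[1, 250\] bpm. Timestamps must be strictly
#' increasing at 1-s resolution.
#'
#' @param participant_id single participant identifier.
#' @param age_years participant age in years.
#' @param device_role `"test"` (1-min wrist tracker) or `"reference"`
#'   (10-s chest strap).
#' @param timestamp `POSIXct` vector (or ISO-8601 strings) of sample times.
#' @param hr_bpm integer heart rates in beats per minute; 0 = no reading.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(participant_id, age_years, device_role, timestamp, hr_bpm) {
  device_role <- match.arg(device_role, c("test", "reference"))
  if (is.character(timestamp)) timestamp <- parse_ts(timestamp)
  s <- structure(
    list(participant_id = as.character(participant_id)[1L],
         age_years = as.numeric(age_years)[1L],
         device_role = device_role,
         nominal_interval_s = if (device_role == "test") 60L else 10L,
         samples = data.frame(timestamp = timestamp,
                              hr_bpm = as.integer(hr_bpm))),
    class = "sensor_stream")
  validate_stream(s)
}

validate_stream <- function(s) {
  hr <- s$samples$hr_bpm
  ts <- s$samples$timestamp
  if (length(hr) != length(ts)) stopf("timestamp/hr length mismatch")
  if (any(!is.finite(hr)) || any(hr < 0L) || any(hr > 250L)) {
    stopf("hr_bpm out of range [0, 250] in stream for %s", s$participant_id)
  }
  if (length(ts) > 1L) {
    d <- diff(as.numeric(ts))
    if (any(d <= 0)) {
      stopf("timestamps not strictly increasing in stream for %s (duplicate or out-of-order rows)",
            s$participant_id)
    }
  }
  invisible(s)
}

#' @export
print.sensor_stream <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<sensor_stream> participant %s (age %.4g), %s device (%ds nominal), %d samples\n",
              x$participant_id, x$age_years, x$device_role, x$nominal_interval_s, n))
  if (n > 0L) {
    cat(sprintf("  %s .. %s; %d nonzero readings\n",
                format_ts(x$samples$timestamp[1L]), format_ts(x$samples$timestamp[n]),
                sum(x$samples$hr_bpm > 0L)))
  }
  invisible(x)
}

#' Read a heart-rate stream CSV
#'
#' The CSV dialect is fixed: comma-separated UTF-8 with header exactly
#' `participant_id,timestamp,hr_bpm` and naive local ISO-8601 timestamps
#' (`YYYY-MM-DDTHH:MM:SS`). Duplicate timestamps are an error, never
#' silently deduplicated.
#'
#' @param path file path.
#' @param device_role `"test"` or `"reference"`.
#' @param registry participant table from [read_participants()] or
#'   [participants()]; the file's `participant_id` must be registered.
#' @return A [sensor_stream()].
#' @export
read_stream <- function(path, device_role, registry) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  validate_participants(registry)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric"))
  if (!identical(names(df), c("participant_id", "timestamp", "hr_bpm"))) {
    stopf("bad stream CSV header in %s: expected participant_id,timestamp,hr_bpm", path)
  }
  ids <- unique(df$participant_id)
  if (nrow(df) > 0L && length(ids) != 1L) {
    stopf("stream file %s mixes participants: %s", path, paste(ids, collapse = ", "))
  }
  pid <- if (nrow(df) > 0L) ids else NA_character_
  if (nrow(df) > 0L && !pid %in% registry$participant_id) {
    stopf("unknown participant_id '%s' in %s (not in registry)", pid, path)
  }
  if (any(df$hr_bpm != floor(df$hr_bpm), na.rm = TRUE)) {
    stopf("non-integer hr_bpm in %s", path)
  }
  age <- registry$age_years[match(pid, registry$participant_id)]
  sensor_stream(pid, age, device_role, parse_ts(df$timestamp), df$hr_bpm)
}

#' Write a heart-rate stream CSV
#'
#' Inverse of [read_stream()]: the round trip is bit-exact on timestamps and
#' integer heart rates, and zero-valued (no-reading) rows are preserved.
#'
#' @param stream a [sensor_stream()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  df <- data.frame(participant_id = rep_len(stream$participant_id, nrow(stream$samples)),
                   timestamp = format_ts(stream$samples$timestamp),
                   hr_bpm = stream$samples$hr_bpm)
  if (nrow(stream$samples) == 0L) {
    # header-only file for an empty stream
    df <- df[0L, , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write stream to %s", path)
  invisible(path)
}
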