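#' Collapse a sensor stream into clock-minute epochs
#'
#' Epochs are wall-clock minute aligned and half-open: the epoch starting at
#' `t` covers `[t, t + 60 s)`. One epoch is emitted for every clock minute
#' from the minute containing the first sample through the minute containing
#' the last sample, whether or not any sample falls in it. Zero-valued
#' samples are the no-reading sentinel and never contribute: the epoch value
#' is the arithmetic mean of the nonzero samples in the minute,
#' `n_source_samples` counts those samples, and `range_width_bpm` is their
#' max − min (0 when at most one sample contributes). A minute with no
#' nonzero sample gets value 0 and n = 0.
#'
#' @param stream a [sensor_stream()].
#' @return A `data.frame` with columns `start` (POSIXct, minute-aligned),
#'   `value_bpm`, `n_source_samples`, `range_width_bpm`; attributes
#'   `participant_id`, `age_years`, `device_role`.
#' @export
minute_epochs <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  validate_stream(stream)
  ts <- stream$samples$timestamp
  hr <- stream$samples$hr_bpm
  if (length(ts) == 0L) {
    out <- data.frame(start = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"),
                      value_bpm = numeric(0), n_source_samples = integer(0),
                      range_width_bpm = numeric(0))
  } else {
    mins <- floor(as.numeric(ts) / 60)
    first <- mins[1L]
    N <- mins[length(mins)] - first + 1L
    idx <- as.integer(mins - first + 1L)
    nz <- hr > 0L
    value <- numeric(N); nsrc <- integer(N); rng <- numeric(N)
    if (any(nz)) {
      g <- idx[nz]
      v <- as.numeric(hr[nz])
      nsrc <- tabulate(g, nbins = N)
      sums <- numeric(N)
      sums[sort(unique(g))] <- rowsum(v, g)[, 1L]
      value <- ifelse(nsrc > 0L, sums / pmax(nsrc, 1L), 0)
      gf <- factor(g, levels = sort(unique(g)))
      mx <- tapply(v, gf, max)
      mn <- tapply(v, gf, min)
      rng[as.integer(levels(gf))] <- as.numeric(mx - mn)
    }
    out <- data.frame(
      start = as.POSIXct((first + seq_len(N) - 1L) * 60, origin = "1970-01-01", tz = "UTC"),
      value_bpm = value, n_source_samples = nsrc, range_width_bpm = rng)
  }
  attr(out, "participant_id") <- stream$participant_id
  attr(out, "age_years") <- stream$age_years
  attr(out, "device_role") <- stream$device_role
  out
}

#' Pair test and reference streams into common-wear epochs
#'
#' Common wear is a clock minute in which both devices register a nonzero
#' heart rate; all other minutes are excluded, never imputed. The reference
#' value for a minute is the mean of its nonzero 10-s samples (at least
#' `min_reference_samples` required); the difference convention is
#' test − reference, so a negative difference is a test-device underestimate.
#'
#' @param test [sensor_stream()] from the test (1-min) device.
#' @param reference [sensor_stream()] from the reference (10-s) device.
#' @param min_reference_samples minimum number of nonzero 10-s samples the
#'   reference must contribute to a minute (default 1; set 6 to require a
#'   complete minute).
#' @return A `data.frame` of class `paired_epochs`, sorted by `start`, with
#'   columns `participant_id`, `age_years`, `start`, `test_bpm`,
#'   `reference_mean_bpm`, `reference_range_width_bpm`, `difference_bpm`.
#' @export
pair_streams <- function(test, reference, min_reference_samples = 1L) {
  stopifnot(inherits(test, "sensor_stream"), inherits(reference, "sensor_stream"))
  if (!identical(test$participant_id, reference$participant_id)) {
    stopf("cannot pair streams from different participants (%s vs %s)",
          test$participant_id, reference$participant_id)
  }
  et <- minute_epochs(test)
  er <- minute_epochs(reference)
  m <- merge(
    data.frame(start = as.numeric(et$start), test_bpm = et$value_bpm),
    data.frame(start = as.numeric(er$start), reference_mean_bpm = er$value_bpm,
               reference_range_width_bpm = er$range_width_bpm,
               n_ref = er$n_source_samples),
    by = "start")
  keep <- m$test_bpm > 0 & m$reference_mean_bpm > 0 & m$n_ref >= min_reference_samples
  m <- m[keep, , drop = FALSE]
  m <- m[order(m$start), , drop = FALSE]
  out <- data.frame(
    participant_id = rep_len(test$participant_id, nrow(m)),
    age_years = rep_len(test$age_years, nrow(m)),
    start = as.POSIXct(m$start, origin = "1970-01-01", tz = "UTC"),
    test_bpm = m$test_bpm,
    reference_mean_bpm = m$reference_mean_bpm,
    reference_range_width_bpm = m$reference_range_width_bpm,
    difference_bpm = m$test_bpm - m$reference_mean_bpm,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("paired_epochs", "data.frame")
  out
}

#' Combine paired epochs from several participants
#'
#' @param ... `paired_epochs` objects (or a single list of them).
#' @return One pooled `paired_epochs` data frame.
#' @export
pool_pairs <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "data.frame")) xs <- xs[[1L]]
  out <- do.call(rbind, lapply(xs, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("paired_epochs", "data.frame")
  out
}

#' Per-calendar-day wear-time and zone summaries
#'
#' A minute of wear is a clock-minute epoch with a nonzero value; a valid day
#' has at least `valid_day_min` (default 600) worn minutes within one
#' calendar day (midnight to midnight, local time). Worn minutes are
#' classified into Low/MVPA zones using the participant's age; the remaining
#' minutes of the 1440-minute day count as "no valid reading", so
#' `n_noread + n_low + n_mvpa == 1440` for every day.
#'
#' @param stream a [sensor_stream()] (typically the test device's free-living
#'   stream).
#' @param scheme a [zone_scheme()].
#' @param valid_day_min minimum worn minutes for a valid day (default 600).
#' @return A `data.frame` with one row per calendar date touched by the
#'   stream: `participant_id`, `date`, `worn_epochs`, `is_valid_day`,
#'   `n_noread`, `n_low`, `n_mvpa`.
#' @export
daily_wear_summaries <- function(stream, scheme = zone_scheme(), valid_day_min = 600L) {
  ep <- minute_epochs(stream)
  age <- attr(ep, "age_years")
  if (nrow(ep) == 0L) {
    return(data.frame(participant_id = character(0), date = as.Date(character(0)),
                      worn_epochs = integer(0), is_valid_day = logical(0),
                      n_noread = integer(0), n_low = integer(0), n_mvpa = integer(0)))
  }
  date <- as.Date(ep$start, tz = "UTC")
  worn <- ep$value_bpm > 0
  zone <- rep(NA_character_, nrow(ep))
  if (any(worn)) zone[worn] <- as.character(classify_zone(ep$value_bpm[worn], age, scheme))
  days <- sort(unique(date))
  n_low <- n_mvpa <- worn_n <- integer(length(days))
  for (i in seq_along(days)) {
    sel <- date == days[i]
    worn_n[i] <- sum(worn & sel)
    n_low[i] <- sum(sel & !is.na(zone) & zone == "low")
    n_mvpa[i] <- sum(sel & !is.na(zone) & zone == "mvpa")
  }
  data.frame(participant_id = rep_len(attr(ep, "participant_id"), length(days)),
             date = days,
             worn_epochs = worn_n,
             is_valid_day = worn_n >= valid_day_min,
             n_noread = 1440L - worn_n,
             n_low = n_low,
             n_mvpa = n_mvpa,
             stringsAsFactors = FALSE)
}
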