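#' Cross-tabulate MVPA classification by the two devices
#'
#' Builds the 2×2 contingency table of reference-zone (rows) against
#' test-zone (columns) classifications over common-wear paired epochs. Each
#' device's zone is computed from its own value with the epoch's participant
#' age; the reference zone defines truth.
#'
#' @param pairs a nonempty `paired_epochs` data frame.
#' @param scheme a [zone_scheme()].
#' @return An object of class `hr_contingency`: a 2×2 integer matrix with
#'   dimnames `reference` × `test` over levels `low`, `mvpa`.
#' @export
build_contingency <- function(pairs, scheme = zone_scheme()) {
  if (nrow(pairs) == 0L) stopf("build_contingency needs at least one paired epoch")
  if (any(pairs$test_bpm <= 0) || any(pairs$reference_mean_bpm <= 0)) {
    stopf("internal invariant violated: zero-valued epoch survived pairing")
  }
  rz <- classify_zone(pairs$reference_mean_bpm, pairs$age_years, scheme)
  tz <- classify_zone(pairs$test_bpm, pairs$age_years, scheme)
  tab <- table(reference = rz, test = tz)
  m <- matrix(as.integer(tab), 2L, 2L,
              dimnames = list(reference = c("low", "mvpa"), test = c("low", "mvpa")))
  structure(m, class = c("hr_contingency", "matrix"))
}

#' Construct a contingency table from explicit counts
#'
#' @param ref_low_test_low,ref_low_test_mvpa,ref_mvpa_test_low,ref_mvpa_test_mvpa
#'   non-negative integer cell counts (reference zone first in each name).
#' @return An `hr_contingency` matrix.
#' @export
contingency_counts <- function(ref_low_test_low, ref_low_test_mvpa,
                               ref_mvpa_test_low, ref_mvpa_test_mvpa) {
  cells <- c(ref_low_test_low, ref_low_test_mvpa, ref_mvpa_test_low, ref_mvpa_test_mvpa)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stopf("contingency cells must be non-negative integers")
  }
  m <- matrix(as.integer(c(ref_low_test_low, ref_mvpa_test_low,
                           ref_low_test_mvpa, ref_mvpa_test_mvpa)), 2L, 2L,
              dimnames = list(reference = c("low", "mvpa"), test = c("low", "mvpa")))
  structure(m, class = c("hr_contingency", "matrix"))
}

#' @export
print.hr_contingency <- function(x, ...) {
  cat("Reference zone x test zone, common-wear 1-min epochs\n")
  print(unclass(x))
  cat(sprintf("total = %d paired epochs\n", sum(x)))
  invisible(x)
}

#' MVPA-detection diagnostics from a 2×2 table
#'
#' Sensitivity, specificity, positive and negative predictive value with the
#' MVPA zone (per the reference device) as the positive class. Each metric
#' retains its integer numerator and denominator; a metric whose denominator
#' is zero is reported as undefined (`NA`) while the others are still
#' computed.
#'
#' @param x an `hr_contingency` matrix (see [build_contingency()]).
#' @return An object of class `hr_diagnostics`: a list with `tp`, `fp`,
#'   `fn`, `tn`, and per-metric lists `sensitivity`, `specificity`, `ppv`,
#'   `npv`, each holding `value`, `num`, `den`.
#' @examples
#' diagnostic_metrics(contingency_counts(2115, 31, 171, 192))
#' @export
diagnostic_metrics <- function(x) {
  stopifnot(inherits(x, "hr_contingency"))
  if (sum(x) == 0L) stopf("diagnostic_metrics undefined for an all-zero table")
  tp <- x["mvpa", "mvpa"]; fn <- x["mvpa", "low"]
  fp <- x["low", "mvpa"]; tn <- x["low", "low"]
  metric <- function(num, den) {
    list(value = if (den > 0L) num / den else NA_real_,
         num = as.integer(num), den = as.integer(den))
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = metric(tp, tp + fn),
                 specificity = metric(tn, tn + fp),
                 ppv = metric(tp, tp + fp),
                 npv = metric(tn, tn + fn)),
            class = "hr_diagnostics")
}

#' @export
print.hr_diagnostics <- function(x, ...) {
  line <- function(name, m, digits = 1L) {
    if (is.na(m$value)) cat(sprintf("  %-12s undefined (%d/%d)\n", name, m$num, m$den))
    else cat(sprintf("  %-12s %5.*f%% (%d/%d)\n", name, digits, 100 * m$value, m$num, m$den))
  }
  cat("MVPA-detection diagnostics (positive class = reference MVPA)\n")
  line("sensitivity", x$sensitivity)
  line("specificity", x$specificity)
  line("PPV", x$ppv)
  line("NPV", x$npv, digits = 2L)
  invisible(x)
}

validate_day_summaries <- function(days, valid_day_min = 600L) {
  worn <- days$n_low + days$n_mvpa
  if (any(worn != days$worn_epochs)) {
    stopf("day summary invariant violated: worn_epochs != n_low + n_mvpa")
  }
  if (any(days$n_noread + worn != 1440L)) {
    stopf("day summary invariant violated: counts do not sum to 1440")
  }
  if (any(days$is_valid_day != (days$worn_epochs >= valid_day_min))) {
    stopf("day summary invariant violated: is_valid_day inconsistent with the %d-min rule",
          valid_day_min)
  }
  invisible(days)
}

freeliving_rows <- function(ids, valid_days, n_noread, n_low, n_mvpa,
                            sd_daily_mvpa = NA_real_) {
  total <- 1440L * valid_days
  data.frame(
    participant_id = ids,
    valid_days = as.integer(valid_days),
    total_epochs = as.integer(total),
    n_noread = as.integer(n_noread), n_low = as.integer(n_low), n_mvpa = as.integer(n_mvpa),
    pct_noread = ifelse(total > 0, 100 * n_noread / total, NA_real_),
    pct_low = ifelse(total > 0, 100 * n_low / total, NA_real_),
    pct_mvpa = ifelse(total > 0, 100 * n_mvpa / total, NA_real_),
    avg_daily_mvpa_min = ifelse(valid_days > 0, n_mvpa / valid_days, NA_real_),
    avg_daily_mvpa_display = ifelse(valid_days > 0,
                                    round_half_up(n_mvpa / valid_days), NA_real_),
    sd_daily_mvpa_min = sd_daily_mvpa,
    stringsAsFactors = FALSE)
}

#' Free-living wear-time and zone summary over valid days
#'
#' Aggregates per-day wear summaries (see [daily_wear_summaries()]) into a
#' per-participant table plus a pooled `overall` row. Only valid days (at
#' least 600 worn minutes) contribute. Percentages are computed against
#' `valid_days * 1440` total epochs and stored exact; the average daily MVPA
#' minutes (`n_mvpa / valid_days`) is stored exact alongside a
#' half-away-from-zero rounded display value. `sd_daily_mvpa_min` is the SD
#' of per-day MVPA minutes across the contributing valid days.
#'
#' @param day_summaries a data frame from [daily_wear_summaries()] (rows from
#'   several participants may be combined with `rbind`).
#' @param valid_day_min minimum worn minutes defining a valid day.
#' @return A data frame of class `freeliving_summary`, one row per
#'   participant plus an `overall` row. With zero valid days, an explicit
#'   all-zero `overall` row is returned.
#' @export
freeliving_summary <- function(day_summaries, valid_day_min = 600L) {
  validate_day_summaries(day_summaries, valid_day_min)
  v <- day_summaries[day_summaries$is_valid_day, , drop = FALSE]
  if (nrow(v) == 0L) {
    out <- freeliving_rows("overall", 0L, 0L, 0L, 0L)
    class(out) <- c("freeliving_summary", "data.frame")
    return(out)
  }
  ids <- sort(unique(v$participant_id))
  per <- do.call(rbind, lapply(ids, function(id) {
    d <- v[v$participant_id == id, , drop = FALSE]
    freeliving_rows(id, nrow(d), sum(d$n_noread), sum(d$n_low), sum(d$n_mvpa),
                    if (nrow(d) > 1L) stats::sd(d$n_mvpa) else NA_real_)
  }))
  overall <- freeliving_rows("overall", nrow(v), sum(v$n_noread), sum(v$n_low),
                             sum(v$n_mvpa),
                             if (nrow(v) > 1L) stats::sd(v$n_mvpa) else NA_real_)
  out <- rbind(per, overall)
  rownames(out) <- NULL
  class(out) <- c("freeliving_summary", "data.frame")
  out
}

#' Free-living summary from printed per-participant counts
#'
#' Builds the same summary table as [freeliving_summary()] directly from
#' aggregate counts (e.g. a published wear-time table), when the underlying
#' per-day summaries are not available. Per-day SDs cannot be recovered from
#' aggregates and are reported `NA`.
#'
#' @param participant_id character vector of participant labels.
#' @param valid_days,n_noread,n_low,n_mvpa integer vectors, one entry per
#'   participant: number of valid days and epoch counts per zone.
#' @return A `freeliving_summary` data frame with an appended pooled
#'   `overall` row.
#' @export
freeliving_from_counts <- function(participant_id, valid_days, n_noread, n_low, n_mvpa) {
  total <- 1440L * valid_days
  if (any(n_noread + n_low + n_mvpa != total)) {
    stopf("counts must satisfy n_noread + n_low + n_mvpa = 1440 * valid_days")
  }
  per <- freeliving_rows(participant_id, valid_days, n_noread, n_low, n_mvpa)
  overall <- freeliving_rows("overall", sum(valid_days), sum(n_noread),
                             sum(n_low), sum(n_mvpa))
  out <- rbind(per, overall)
  rownames(out) <- NULL
  class(out) <- c("freeliving_summary", "data.frame")
  out
}

#' @export
print.freeliving_summary <- function(x, ...) {
  cat("Free-living wear summary (valid days only)\n")
  disp <- data.frame(
    participant = x$participant_id,
    `valid days` = x$valid_days,
    epochs = x$total_epochs,
    `noread %` = sprintf("%.1f", x$pct_noread),
    `low %` = sprintf("%.1f", x$pct_low),
    `mvpa %` = sprintf("%.1f", x$pct_mvpa),
    `MVPA min/day` = ifelse(is.na(x$avg_daily_mvpa_display), "-",
                            sprintf("%d", as.integer(x$avg_daily_mvpa_display))),
    check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Cohort adherence over follow-up
#'
#' Indexes each participant's days by days since their first valid day
#' (index 1 = the first valid day) and, for each follow-up day index, counts
#' the participants contributing a valid day and summarizes worn minutes
#' (mean and SD across those valid days; SD is `NA` with a single
#' contributor).
#'
#' @param day_summaries combined per-day summaries for a cohort.
#' @return A data frame with columns `day_index`, `n_valid`,
#'   `mean_worn_min`, `sd_worn_min`.
#' @export
adherence_curve <- function(day_summaries) {
  v <- day_summaries[day_summaries$is_valid_day, , drop = FALSE]
  if (nrow(v) == 0L) {
    return(data.frame(day_index = integer(0), n_valid = integer(0),
                      mean_worn_min = numeric(0), sd_worn_min = numeric(0)))
  }
  first <- tapply(as.integer(v$date), v$participant_id, min)
  idx <- as.integer(v$date) - first[v$participant_id] + 1L
  days <- sort(unique(idx))
  data.frame(
    day_index = days,
    n_valid = vapply(days, function(d) sum(idx == d), integer(1)),
    mean_worn_min = vapply(days, function(d) mean(v$worn_epochs[idx == d]), numeric(1)),
    sd_worn_min = vapply(days, function(d) {
      w <- v$worn_epochs[idx == d]
      if (length(w) > 1L) stats::sd(w) else NA_real_
    }, numeric(1)))
}
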