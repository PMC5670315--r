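# Orchestration: run the validation and free-living analyses end to end and
# write report bundles (CSV + JSON). Outputs are pure functions of the
# inputs: rerunning a step on the same data yields byte-identical files.

resolve_cohort <- function(x) {
  if (inherits(x, "hr_cohort")) x else read_cohort(x)
}

write_table <- function(df, path) {
  df2 <- df
  for (nm in names(df2)) {
    if (inherits(df2[[nm]], "POSIXct")) df2[[nm]] <- format_ts(df2[[nm]])
    if (inherits(df2[[nm]], "Date")) df2[[nm]] <- format(df2[[nm]], "%Y-%m-%d")
  }
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the validation-session analysis and write its report bundle
#'
#' Pairs each participant's validation test and reference streams into
#' common-wear epochs, fits the agreement analysis ([hr_agreement()]),
#' builds the MVPA-detection contingency table and diagnostics, and the
#' decile and Bland-Altman plot data. Participants lacking either stream are
#' reported as excluded, never silently dropped. A filter-attrition log
#' (possible epochs, paired epochs, per-stratum n) is written alongside the
#' tables.
#'
#' Files written to `out_dir`: `paired_epochs.csv`, `agreement.csv`,
#' `contingency.csv`, `diagnostics.csv`, `deciles.csv`, `bland_altman.csv`,
#' `attrition.json`.
#'
#' @param cohort an `hr_cohort` or a directory written by [write_cohort()].
#' @param out_dir output directory (created if needed).
#' @param scheme a [zone_scheme()].
#' @param min_reference_samples passed to [pair_streams()].
#' @return Invisibly, a list with `pairs`, `fit`, `contingency`,
#'   `diagnostics`, `deciles`, `attrition`.
#' @export
run_validation <- function(cohort, out_dir, scheme = zone_scheme(),
                           min_reference_samples = 1L) {
  cohort <- resolve_cohort(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sort(cohort$participants$participant_id)
  excluded <- character(0)
  pair_list <- list()
  possible <- 0L
  for (id in ids) {
    v <- cohort$validation[[id]]
    if (is.null(v) || is.null(v$test) || is.null(v$reference)) {
      excluded <- c(excluded, id)
      next
    }
    et <- minute_epochs(v$test); er <- minute_epochs(v$reference)
    possible <- possible + length(union(as.numeric(et$start), as.numeric(er$start)))
    pair_list[[id]] <- pair_streams(v$test, v$reference,
                                    min_reference_samples = min_reference_samples)
  }
  if (length(pair_list) == 0L) stopf("no participant has both validation streams")
  pairs <- pool_pairs(pair_list)
  fit <- hr_agreement(pairs, scheme)
  tab <- build_contingency(pairs, scheme)
  diag <- diagnostic_metrics(tab)
  dec <- decile_summary(pairs)

  write_table(as.data.frame(pairs), file.path(out_dir, "paired_epochs.csv"))
  write_table(fit$table, file.path(out_dir, "agreement.csv"))
  write_table(data.frame(reference_zone = rep(rownames(tab), 2),
                         test_zone = rep(colnames(tab), each = 2),
                         n = as.integer(tab)),
              file.path(out_dir, "contingency.csv"))
  write_table(data.frame(
    metric = c("sensitivity", "specificity", "ppv", "npv"),
    value = c(diag$sensitivity$value, diag$specificity$value,
              diag$ppv$value, diag$npv$value),
    num = c(diag$sensitivity$num, diag$specificity$num, diag$ppv$num, diag$npv$num),
    den = c(diag$sensitivity$den, diag$specificity$den, diag$ppv$den, diag$npv$den)),
    file.path(out_dir, "diagnostics.csv"))
  write_table(as.data.frame(dec), file.path(out_dir, "deciles.csv"))
  zl <- zone_strata(pairs, scheme)
  write_table(data.frame(zone = as.character(zl),
                         mean_bpm = (pairs$test_bpm + pairs$reference_mean_bpm) / 2,
                         diff_bpm = pairs$difference_bpm),
              file.path(out_dir, "bland_altman.csv"))
  attrition <- list(
    possible_epochs = possible,
    paired_epochs = nrow(pairs),
    excluded_participants = excluded,
    n_by_zone = as.list(table(zl)),
    n_by_participant = as.list(table(pairs$participant_id)))
  jsonlite::write_json(attrition, file.path(out_dir, "attrition.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(pairs = pairs, fit = fit, contingency = tab,
                 diagnostics = diag, deciles = dec, attrition = attrition))
}

#' Run the free-living analysis and write its report bundle
#'
#' Computes per-day wear summaries from each participant's free-living test
#' stream, the per-participant and pooled wear/zone summary over valid days,
#' and the cohort adherence curve.
#'
#' Files written to `out_dir`: `day_summaries.csv`, `freeliving.csv`,
#' `adherence.csv`.
#'
#' @param cohort an `hr_cohort` or a directory written by [write_cohort()].
#' @param out_dir output directory (created if needed).
#' @param scheme a [zone_scheme()].
#' @param valid_day_min minimum worn minutes defining a valid day.
#' @return Invisibly, a list with `days`, `summary`, `adherence`.
#' @export
run_freeliving <- function(cohort, out_dir, scheme = zone_scheme(),
                           valid_day_min = 600L) {
  cohort <- resolve_cohort(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sort(cohort$participants$participant_id)
  day_list <- list()
  for (id in ids) {
    f <- cohort$freeliving[[id]]
    if (is.null(f) || nrow(f$samples) == 0L) {
      warning(sprintf("participant %s has no free-living data", id), call. = FALSE)
      next
    }
    day_list[[id]] <- daily_wear_summaries(f, scheme, valid_day_min)
  }
  days <- if (length(day_list) > 0L) do.call(rbind, day_list) else
    data.frame(participant_id = character(0), date = as.Date(character(0)),
               worn_epochs = integer(0), is_valid_day = logical(0),
               n_noread = integer(0), n_low = integer(0), n_mvpa = integer(0))
  rownames(days) <- NULL
  summ <- freeliving_summary(days, valid_day_min)
  adh <- adherence_curve(days)
  write_table(days, file.path(out_dir, "day_summaries.csv"))
  write_table(as.data.frame(summ), file.path(out_dir, "freeliving.csv"))
  write_table(adh, file.path(out_dir, "adherence.csv"))
  invisible(list(days = days, summary = summ, adherence = adh))
}
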