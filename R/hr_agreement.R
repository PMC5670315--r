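#' Fit the full device-agreement analysis on paired epochs
#'
#' One call computing the overall, zone-stratified (reference-defined Low vs
#' MVPA) and per-participant agreement statistics on a set of common-wear
#' paired epochs: ICC(A,1) with its F-based 95% CI and strength label, the
#' paired mean difference with 95% CI and p-value, and Bland-Altman limits.
#' This is the estimator at the centre of the package; the individual
#' statistics are also available directly via [icc_a1()],
#' [mean_difference()] and [bland_altman()].
#'
#' @param pairs a `paired_epochs` data frame (one or many participants; pool
#'   with [pool_pairs()]).
#' @param scheme a [zone_scheme()] used for the zone stratification.
#' @return An object of class `hr_agreement` with components
#'   `table` (one row per stratum: overall, zones, participants),
#'   `overall`, `by_zone`, `by_participant` (full `stratified_agreement`
#'   objects), `pairs`, and `scheme`.
#' @examples
#' sc <- cohort_scenario(n_participants = 2, followup_days = 0, seed = 7)
#' coh <- simulate_cohort(sc)
#' pairs <- pool_pairs(lapply(coh$validation, function(v)
#'   pair_streams(v$test, v$reference)))
#' fit <- hr_agreement(pairs)
#' print(fit)
#' @export
hr_agreement <- function(pairs, scheme = zone_scheme()) {
  stopifnot(inherits(pairs, "data.frame"))
  if (nrow(pairs) < 3L) stopf("hr_agreement needs at least 3 paired epochs")
  overall <- stratified_agreement(pairs, rep("overall", nrow(pairs)))
  by_zone <- stratified_agreement(pairs, zone_strata(pairs, scheme))
  by_part <- stratified_agreement(pairs, pairs$participant_id)

  row_of <- function(name, res) {
    md <- res$mean_difference; ic <- res$icc
    data.frame(
      stratum = name, n = res$n,
      icc = if (is.null(ic)) NA_real_ else ic$icc,
      icc_lo = if (is.null(ic)) NA_real_ else ic$ci95[1L],
      icc_hi = if (is.null(ic)) NA_real_ else ic$ci95[2L],
      strength = if (is.null(ic)) NA_character_ else ic$strength,
      mean_diff = if (is.null(md)) NA_real_ else md$mean_diff_bpm,
      diff_lo = if (is.null(md)) NA_real_ else md$ci95[1L],
      diff_hi = if (is.null(md)) NA_real_ else md$ci95[2L],
      p_value = if (is.null(md)) NA_real_ else md$p_value,
      stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row_of("overall", overall$overall),
    do.call(rbind, lapply(names(by_zone), function(z)
      row_of(paste0("zone:", z), by_zone[[z]]))),
    do.call(rbind, lapply(names(by_part), function(p)
      row_of(paste0("participant:", p), by_part[[p]]))))
  rownames(tab) <- NULL
  structure(list(table = tab, overall = overall$overall, by_zone = by_zone,
                 by_participant = by_part, pairs = pairs, scheme = scheme),
            class = "hr_agreement")
}

#' @export
print.hr_agreement <- function(x, digits = 3, ...) {
  cat(sprintf("Heart-rate device agreement on %d common-wear 1-min epochs\n",
              nrow(x$pairs)))
  tab <- x$table
  fmt <- function(v, d = digits) ifelse(is.na(v), "-", formatC(v, digits = d, format = "fg"))
  disp <- data.frame(
    stratum = tab$stratum, n = tab$n,
    `ICC (95% CI)` = ifelse(is.na(tab$icc), "-",
      sprintf("%.2f (%.2f-%.2f)", tab$icc, tab$icc_lo, tab$icc_hi)),
    strength = ifelse(is.na(tab$strength), "-", tab$strength),
    `diff (95% CI)` = ifelse(is.na(tab$mean_diff), "-",
      sprintf("%.2f (%.2f to %.2f)", tab$mean_diff, tab$diff_lo, tab$diff_hi)),
    p = ifelse(is.na(tab$p_value), "-",
      ifelse(tab$p_value < 0.001, "<.001", sprintf("%.3f", tab$p_value))),
    check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @export
summary.hr_agreement <- function(object, ...) {
  cat("Overall agreement\n")
  if (!is.null(object$overall$icc)) print(object$overall$icc)
  if (!is.null(object$overall$mean_difference)) print(object$overall$mean_difference)
  if (!is.null(object$overall$bland_altman)) print(object$overall$bland_altman)
  cat("\nBy reference heart-rate zone\n")
  for (z in names(object$by_zone)) {
    r <- object$by_zone[[z]]
    cat(sprintf("  %s (n = %d): ", z, r$n))
    if (is.null(r$mean_difference)) cat("insufficient data\n")
    else cat(sprintf("bias %.2f bpm, ICC %s\n", r$mean_difference$mean_diff_bpm,
                     if (is.null(r$icc)) "-" else sprintf("%.2f", r$icc$icc)))
  }
  invisible(object)
}

#' @export
coef.hr_agreement <- function(object, ...) {
  c(icc = if (is.null(object$overall$icc)) NA_real_ else object$overall$icc$icc,
    mean_diff_bpm = if (is.null(object$overall$mean_difference)) NA_real_
                    else object$overall$mean_difference$mean_diff_bpm)
}

#' @export
residuals.hr_agreement <- function(object, ...) {
  object$pairs$difference_bpm
}

#' Bland-Altman plot of a fitted agreement analysis
#'
#' @param x an `hr_agreement` object.
#' @param zone `"all"`, `"low"` or `"mvpa"`: which reference-zone subset to
#'   plot.
#' @param ... passed to [plot.bland_altman()].
#' @export
plot.hr_agreement <- function(x, zone = c("all", "low", "mvpa"), ...) {
  zone <- match.arg(zone)
  if (zone == "all") {
    plot(x$overall$bland_altman,
         main = "Bland-Altman, all common-wear epochs", ...)
  } else {
    r <- x$by_zone[[zone]]
    if (is.null(r$bland_altman)) stopf("insufficient data in zone '%s'", zone)
    plot(r$bland_altman, main = sprintf("Bland-Altman, %s zone", zone), ...)
  }
  invisible(x)
}
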