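#' Paired mean difference with t-based inference
#'
#' Mean of the per-epoch differences (test − reference) with its standard
#' error, two-sided 95% confidence interval and paired-t p-value. Differences
#' with zero variance are a degenerate case: the point estimate is returned
#' with `se = 0`, a collapsed CI, and the t statistic and p-value flagged
#' undefined (`NA`) rather than fabricated.
#'
#' @param x a `paired_epochs` data frame (see [pair_streams()]) or a numeric
#'   vector of differences.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `mean_difference`: list with `n`,
#'   `mean_diff_bpm`, `se_bpm`, `ci95`, `t_statistic`, `p_value`,
#'   `degenerate`.
#' @export
mean_difference <- function(x, conf_level = 0.95) {
  d <- if (is.numeric(x)) x else x$difference_bpm
  n <- length(d)
  if (n < 2L) stopf("mean_difference needs at least 2 paired epochs, got %d", n)
  m <- mean(d)
  s <- stats::sd(d)
  se <- s / sqrt(n)
  if (se == 0) {
    res <- list(n = n, mean_diff_bpm = m, se_bpm = 0, ci95 = c(m, m),
                t_statistic = NA_real_, p_value = NA_real_, degenerate = TRUE)
  } else {
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1L)
    tstat <- m / se
    res <- list(n = n, mean_diff_bpm = m, se_bpm = se,
                ci95 = c(m - tq * se, m + tq * se),
                t_statistic = tstat,
                p_value = 2 * stats::pt(-abs(tstat), df = n - 1L),
                degenerate = FALSE)
  }
  structure(res, class = "mean_difference")
}

#' @export
print.mean_difference <- function(x, ...) {
  cat(sprintf("Mean difference (test - reference): %.2f bpm (95%% CI %.2f to %.2f), n = %d\n",
              x$mean_diff_bpm, x$ci95[1L], x$ci95[2L], x$n))
  if (x$degenerate) cat("  constant differences: t and p undefined\n")
  else cat(sprintf("  SE %.3f, t = %.2f, p = %.3g\n", x$se_bpm, x$t_statistic, x$p_value))
  invisible(x)
}

# Two-way ANOVA mean squares without replication for an n x k ratings matrix:
# rows = subjects (epochs), columns = raters (devices).
two_way_mean_squares <- function(M) {
  n <- nrow(M); k <- ncol(M)
  rm_ <- rowMeans(M); cm_ <- colMeans(M); gm <- mean(M)
  MSR <- k * sum((rm_ - gm)^2) / (n - 1)
  MSC <- n * sum((cm_ - gm)^2) / (k - 1)
  resid <- M - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + gm
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  list(MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k)
}

#' Single-measure two-way absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Agreement between the two devices treated as fixed rater columns over
#' 1-min epochs as subjects, in the absolute-agreement form that penalizes
#' systematic offsets:
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the rows (subjects), columns
#' (raters) and error mean squares of the two-way ANOVA without replication.
#' The confidence interval is the F-based interval of McGraw & Wong for this
#' ICC form. A strength label is attached: weak below .5, strong above .7,
#' moderate on the closed interval \[.5, .7\].
#'
#' @param x a `paired_epochs` data frame, or an n × k numeric matrix of
#'   ratings (n subjects, k raters).
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci95`, `n_subjects`,
#'   `k_raters`, `ms` (list MSR/MSC/MSE), `strength`.
#' @export
icc_a1 <- function(x, conf_level = 0.95) {
  M <- if (is.matrix(x)) x else cbind(test = x$test_bpm, reference = x$reference_mean_bpm)
  if (ncol(M) < 2L) stopf("icc_a1 needs at least 2 rater columns")
  n <- nrow(M)
  if (n < 3L) stopf("icc_a1 needs at least 3 subjects (epochs), got %d", n)
  if (max(M) == min(M)) stopf("icc_a1 undefined: zero total variance")
  ms <- two_way_mean_squares(M)
  k <- ms$k
  icc <- (ms$MSR - ms$MSE) /
    (ms$MSR + (k - 1) * ms$MSE + (k / n) * (ms$MSC - ms$MSE))
  alpha <- 1 - conf_level
  if (ms$MSE == 0 && ms$MSC == ms$MSE) {
    ci <- c(1, 1)  # perfect agreement: interval degenerate at 1
  } else if (icc >= 1) {
    ci <- c(1, 1)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * ms$MSC + b * ms$MSE)^2 /
      ((a * ms$MSC)^2 / (k - 1) + (b * ms$MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
    FU <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
    lo <- n * (ms$MSR - FL * ms$MSE) /
      (FL * (k * ms$MSC + (k * n - k - n) * ms$MSE) + n * ms$MSR)
    hi <- n * (FU * ms$MSR - ms$MSE) /
      (k * ms$MSC + (k * n - k - n) * ms$MSE + n * FU * ms$MSR)
    ci <- c(lo, hi)
  }
  structure(list(icc = icc, ci95 = ci, n_subjects = n, k_raters = k,
                 ms = ms[c("MSR", "MSC", "MSE")],
                 strength = icc_strength(icc)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (95%% CI %.3f to %.3f), %s agreement; n = %d epochs x %d devices\n",
              x$icc, x$ci95[1L], x$ci95[2L], x$strength, x$n_subjects, x$k_raters))
  invisible(x)
}

#' Qualitative strength label for an ICC
#'
#' Weak below .5, strong above .7; the closed interval \[.5, .7\] (including
#' both endpoints) is moderate.
#'
#' @param icc numeric ICC value(s).
#' @return Character vector in `{"weak", "moderate", "strong"}`.
#' @export
icc_strength <- function(icc) {
  ifelse(icc < 0.5, "weak", ifelse(icc > 0.7, "strong", "moderate"))
}

#' Bland-Altman agreement analysis
#'
#' Mean bias and 95% limits of agreement (bias ± 1.96 × SD of the
#' differences, the conventional large-sample form), together with the
#' per-pair (mean, difference) coordinates used for plotting.
#'
#' @param x a `paired_epochs` data frame, or a list with numeric `test` and
#'   `reference` vectors of equal length.
#' @return An object of class `bland_altman`: `n`, `bias_bpm`,
#'   `sd_diff_bpm`, `loa_lower_bpm`, `loa_upper_bpm`, `points`
#'   (data frame `mean_bpm`, `diff_bpm`).
#' @export
bland_altman <- function(x) {
  if (inherits(x, "data.frame")) {
    t_ <- x$test_bpm; r_ <- x$reference_mean_bpm
  } else {
    t_ <- x$test; r_ <- x$reference
  }
  n <- length(t_)
  if (n < 2L) stopf("bland_altman needs at least 2 pairs, got %d", n)
  d <- t_ - r_
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(n = n, bias_bpm = bias, sd_diff_bpm = s,
                 loa_lower_bpm = bias - 1.96 * s,
                 loa_upper_bpm = bias + 1.96 * s,
                 points = data.frame(mean_bpm = (t_ + r_) / 2, diff_bpm = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f bpm, 95%% LoA [%.2f, %.2f], n = %d\n",
              x$bias_bpm, x$loa_lower_bpm, x$loa_upper_bpm, x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$points$mean_bpm, x$points$diff_bpm,
                 xlab = "Mean of devices (bpm)",
                 ylab = "Difference, test - reference (bpm)", ...)
  graphics::abline(h = c(x$bias_bpm, x$loa_lower_bpm, x$loa_upper_bpm),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Agreement statistics within strata
#'
#' Runs [mean_difference()], [icc_a1()] and [bland_altman()] within each
#' stratum of the paired epochs. Strata whose size falls below an operation's
#' minimum are reported with an explicit `insufficient` marker, never dropped
#' silently.
#'
#' @param pairs a `paired_epochs` data frame.
#' @param strata either a vector/factor of stratum labels (one per pair) or a
#'   function taking the pairs data frame and returning such labels. Every
#'   pair must map to exactly one stratum.
#' @return A named list of class `stratified_agreement`; per stratum a list
#'   with `n`, `mean_difference`, `icc`, `bland_altman`, `insufficient`
#'   (character vector of operations skipped for lack of data).
#' @export
stratified_agreement <- function(pairs, strata) {
  lab <- if (is.function(strata)) strata(pairs) else strata
  if (length(lab) != nrow(pairs)) stopf("strata labels must match the number of pairs")
  if (anyNA(lab)) stopf("every pair must map to exactly one stratum (NA label found)")
  lab <- as.factor(lab)
  out <- lapply(levels(lab), function(lv) {
    p <- pairs[lab == lv, , drop = FALSE]
    n <- nrow(p)
    insuff <- character(0)
    md <- ba <- icc <- NULL
    if (n >= 2L) {
      md <- mean_difference(p)
      ba <- bland_altman(p)
    } else insuff <- c(insuff, "mean_difference", "bland_altman")
    if (n >= 3L) {
      icc <- tryCatch(icc_a1(p), error = function(e) NULL)
      if (is.null(icc)) insuff <- c(insuff, "icc")
    } else insuff <- c(insuff, "icc")
    list(n = n, mean_difference = md, icc = icc, bland_altman = ba,
         insufficient = insuff)
  })
  names(out) <- levels(lab)
  structure(out, class = "stratified_agreement")
}

#' Reference-zone stratum labels for paired epochs
#'
#' Zone stratification uses the reference device's value (the reference
#' defines truth) with each epoch's participant age.
#'
#' @param pairs a `paired_epochs` data frame.
#' @param scheme a [zone_scheme()].
#' @return Factor of `"low"` / `"mvpa"` labels, one per pair.
#' @export
zone_strata <- function(pairs, scheme = zone_scheme()) {
  classify_zone(pairs$reference_mean_bpm, pairs$age_years, scheme)
}

#' Decile box-plot summaries of paired epochs
#'
#' Rank-orders the paired epochs by the reference mean (ties broken by epoch
#' start time, then participant id), splits them into 10 rank-ordered groups
#' whose sizes differ by at most one, and returns Tukey five-number summaries
#' (min, lower hinge, median, upper hinge, max) per decile for the reference
#' means, the test values, and the within-epoch reference range widths.
#'
#' @param pairs a `paired_epochs` data frame with at least 10 rows.
#' @return An object of class `decile_summary`: data frame with one row per
#'   decile and columns `decile`, `n`, `ref_lo`/`ref_hi` (decile boundaries)
#'   and `<series>_{min,q1,med,q3,max}` for series `ref`, `test`, `width`.
#' @export
decile_summary <- function(pairs) {
  n <- nrow(pairs)
  if (n < 10L) stopf("decile_summary needs at least 10 paired epochs, got %d", n)
  ord <- order(pairs$reference_mean_bpm, as.numeric(pairs$start), pairs$participant_id)
  p <- pairs[ord, , drop = FALSE]
  bounds <- floor(n * (0:10) / 10)
  five <- function(v) {
    f <- stats::fivenum(v)
    c(min = f[1L], q1 = f[2L], med = f[3L], q3 = f[4L], max = f[5L])
  }
  rows <- lapply(1:10, function(i) {
    sel <- (bounds[i] + 1L):bounds[i + 1L]
    r <- five(p$reference_mean_bpm[sel])
    t_ <- five(p$test_bpm[sel])
    w <- five(p$reference_range_width_bpm[sel])
    data.frame(decile = i, n = length(sel),
               ref_lo = min(p$reference_mean_bpm[sel]),
               ref_hi = max(p$reference_mean_bpm[sel]),
               ref_min = r[1L], ref_q1 = r[2L], ref_med = r[3L], ref_q3 = r[4L], ref_max = r[5L],
               test_min = t_[1L], test_q1 = t_[2L], test_med = t_[3L], test_q3 = t_[4L], test_max = t_[5L],
               width_min = w[1L], width_q1 = w[2L], width_med = w[3L], width_q3 = w[4L], width_max = w[5L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("decile_summary", "data.frame")
  out
}
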