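#' Heart-rate zone scheme
#'
#' Age-based two-zone scheme: maximal heart rate is `max_hr_intercept - age`
#' (the conventional 220 − age rule) and a 1-min epoch is moderate-to-vigorous
#' physical activity (MVPA) when the heart rate reaches at least
#' `mvpa_threshold_fraction` of maximal heart rate; otherwise it is Low.
#' The boundary itself (exactly 50\% by default) classifies as MVPA.
#'
#' @param max_hr_intercept intercept of the age-predicted maximal heart-rate
#'   formula, in bpm (default 220).
#' @param mvpa_threshold_fraction MVPA threshold as a fraction of maximal
#'   heart rate, in (0, 1) (default 0.50).
#' @return An object of class `zone_scheme`.
#' @examples
#' sc <- zone_scheme()
#' max_heart_rate(25, sc)          # 195
#' classify_zone(97.5, 25, sc)     # boundary -> "mvpa"
#' @export
zone_scheme <- function(max_hr_intercept = 220, mvpa_threshold_fraction = 0.50) {
  if (!(mvpa_threshold_fraction > 0 && mvpa_threshold_fraction < 1)) {
    stopf("mvpa_threshold_fraction must lie in (0, 1)")
  }
  structure(list(max_hr_intercept = max_hr_intercept,
                 mvpa_threshold_fraction = mvpa_threshold_fraction),
            class = "zone_scheme")
}

#' @export
print.zone_scheme <- function(x, ...) {
  cat(sprintf("<zone_scheme> max HR = %g - age; MVPA at >= %g%% of max HR\n",
              x$max_hr_intercept, 100 * x$mvpa_threshold_fraction))
  invisible(x)
}

#' Age-predicted maximal heart rate
#'
#' @param age_years age in years (vectorized); fractional ages accepted, not
#'   rounded.
#' @param scheme a [zone_scheme()].
#' @return Maximal heart rate in bpm.
#' @export
max_heart_rate <- function(age_years, scheme = zone_scheme()) {
  scheme$max_hr_intercept - age_years
}

#' Relative exercise intensity
#'
#' Heart rate as a fraction of age-predicted maximal heart rate. May exceed 1.
#' A zero heart rate encodes "no reading" and must be filtered out upstream;
#' passing one is an error.
#'
#' @param hr_bpm positive heart rate(s) in bpm.
#' @inheritParams max_heart_rate
#' @return Fraction(s) of maximal heart rate.
#' @export
relative_intensity <- function(hr_bpm, age_years, scheme = zone_scheme()) {
  if (any(hr_bpm <= 0)) {
    stopf("relative_intensity undefined for hr_bpm <= 0 (zero encodes no reading)")
  }
  hr_bpm / max_heart_rate(age_years, scheme)
}

#' Classify heart rate into Low vs MVPA zone
#'
#' MVPA iff relative intensity is at or above the scheme threshold (the
#' boundary is MVPA); Low otherwise. Vectorized over `hr_bpm` and `age_years`.
#'
#' @inheritParams relative_intensity
#' @return A factor with levels `"low"`, `"mvpa"`.
#' @export
classify_zone <- function(hr_bpm, age_years, scheme = zone_scheme()) {
  ri <- relative_intensity(hr_bpm, age_years, scheme)
  factor(ifelse(ri >= scheme$mvpa_threshold_fraction, "mvpa", "low"),
         levels = c("low", "mvpa"))
}
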