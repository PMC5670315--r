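---
title: "Methods: heart-rate device agreement under free-living conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-rate device agreement under free-living conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wearhr)
```

`wearhr` quantifies how well a wrist-worn optical heart-rate tracker agrees
with a chest-strap reference when both are worn in daily life, and how
reliably the tracker detects minutes of moderate-to-vigorous physical
activity (MVPA). This vignette is the package's account of the statistical
model, the choices that were genuinely open, and what the synthetic cohort
does and does not establish.

## The measurement problem

The two devices report on different schedules — the tracker one value per
minute, the reference one value every 10 seconds — and both drop out
(nonwear, poor contact), encoded as a heart rate of 0. The unit of analysis
is the wall-clock minute: the epoch starting at time *t* covers
[*t*, *t* + 60 s). The reference value for a minute is the arithmetic mean
of its *nonzero* 10-s samples. Averaging in zeros would bias the reference
downward, because zero is a missing-data sentinel, not a heart rate; a
complete minute contributes six samples, and `min_reference_samples`
(default 1) lets the analyst require a full minute instead. A *common-wear*
epoch — nonzero on both devices — is the inclusion criterion for all paired
analyses; unpaired minutes are excluded, never imputed. The difference
convention is test − reference, so underestimation by the tracker is
negative.

Two conventions here are the package's own, since by-minute consumer logs do
not document them: epochs are aligned to clock minutes (half-open
intervals), and a test reading timestamped mid-minute is assigned to the
minute containing it (floored), never split. "Possible epochs" in the
attrition log is the union of minutes spanned by either device's stream —
a bookkeeping convention for the audit trail, not a quantity with an
external definition.

## Agreement statistics

`hr_agreement()` fits three complementary summaries on the paired epochs,
overall, within reference-defined heart-rate zones, and per participant.

**ICC(A,1).** The intraclass correlation in its single-measure, two-way,
absolute-agreement form (McGraw & Wong's ICC(A,1)), with subjects = epochs
and raters = the two devices:

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)},$$

computed from the two-way ANOVA mean squares without replication (rows =
epochs, columns = devices, \(k = 2\)). The *absolute-agreement* form is the
right one for device validation because it charges systematic offsets to the
disagreement term: adding a constant to one device inflates \(MS_C\) and can
only lower the coefficient (the consistency form would ignore it entirely).
The 95% CI is the F-based interval for this form, with the Satterthwaite
degrees of freedom of the mixed mean-square denominator. Strength labels
follow the common weak/moderate/strong convention (< .5, [.5, .7], > .7);
the published rule this mirrors leaves the two boundary points formally
ambiguous, and the package resolves both into "moderate".

For the "overall" coefficient, epochs are pooled across participants (each
participant's coefficients are also reported). Pooling treats epochs as
exchangeable subjects and ignores within-participant autocorrelation; so
does the paired t-test on pooled epochs. Both are deliberate mirrors of
standard practice in device-validation reports and are statistically
anticonservative — CIs and p-values on pooled epochs are too narrow.
This is a documented limitation, not a bug.

**Mean difference.** Mean of the differences with \(SE = s/\sqrt{n}\),
two-sided paired-t CI and p-value. When every difference is identical the
SE is zero; the estimate is still reported but t and p are flagged
undefined (`NA`) rather than fabricated.

**Bland–Altman.** Bias ± 1.96 SD of the differences. The large-sample 1.96
is used, not a t quantile, matching the conventional form at the epoch
counts this design produces (thousands); no repeated-measures variance
correction is applied (same pooling caveat as above).

**Deciles.** For the descriptive by-intensity comparison, epochs are ranked
by reference mean (ties broken by start time, then participant id, so output
is deterministic), split into ten rank groups whose sizes differ by at most
one (boundaries at `floor(n*(0:10)/10)`), and summarized by Tukey
five-number summaries — the statistics a box plot draws.

## Zones and detection

Maximal heart rate is the age-predicted 220 − age (bpm); relative intensity
is the heart rate divided by that; MVPA is ≥ 50% of maximal, with the
boundary classified as MVPA (the threshold stratum is defined by "at
least"). Fractional ages are used as-is. For the 2×2 detection table each
device classifies its own value — reference rows define truth — and
sensitivity, specificity, PPV and NPV are stored as exact integer ratios,
with display rounding applied only in print methods (half away from zero
for the daily-minutes column, e.g. 3685/30 → 123).

Wear-time rules for the free-living month: any nonzero tracker minute is
wear; a calendar day (local midnight to midnight) with ≥ 600 worn minutes
is a valid day; per-day zone counts plus no-reading minutes always sum to
1440, an invariant the summary functions verify on their inputs. The
adherence curve indexes days from each participant's first valid day.

## The synthetic cohort

No raw streams ship with validation studies of this kind, so the package
generates its own, with enough structure that every pipeline stage —
parsing, epoching, pairing, agreement, detection, compliance — can be tested
against known ground truth.

*Truth process.* Activity is a semi-Markov chain over
nonwear/rest/light/MVPA with exponential dwell times (means 12/30/10/6 min;
a 30-s floor avoids degenerate flicker). Within a bout, the per-second true
heart rate is a mean-reverting AR(1) around a bout-specific target, time
constant 30 s — so transitions between states play out over roughly a
minute, emulating the lag with which heart rate follows activity change.
Rest targets are anchored at the participant's resting heart rate
(×1.00–1.06); light and MVPA targets are uniform on 0.40–0.47 and
0.62–0.90 of maximal heart rate. Resting heart rate is drawn from
N(65, 6²) bpm truncated to [50, 85] — a plausible adult range, a modelling
constant rather than an estimate from any dataset.

*Observation.* The reference samples truth every 10 s plus N(0, 1.5²) noise;
the test device averages truth over the minute and adds the participant's
error \(\beta_{0i} + \beta_{1i}\max(0, \bar h - \mathrm{rest}_i)\) plus
N(0, 3²) noise, with \(\beta_{0i} \sim N(-4, 1.3^2)\) bpm and
\(\beta_{1i} \sim N(-0.15, 0.04^2)\) bpm/bpm. Readings are rounded to
integers, floored at 25 bpm (a physiological guard that never binds in
practice), and dropped to 0 at 2% per reference sample and 4% per test
minute. Nonwear always emits 0.

*Calibration.* The intercept/slope defaults are tuning constants chosen so
the expected zone-stratified biases reproduce the published low-vs-MVPA
pattern: about −4 to −5 bpm in the Low zone and mid-teens in the MVPA zone.
One subtlety drove the MVPA target range upward (0.62–0.90 rather than a
range starting nearer the 0.5 threshold): epochs at the edges of MVPA bouts
— ramps in and out — land just above the zone boundary, where the
intensity-dependent error is small, and pull the MVPA-stratum mean bias
toward zero. Centering bout targets higher keeps the stratum mean near the
intended −15 bpm without touching the error model itself. These parameters
are inputs to the simulation, never asserted as estimates of any real
device's error.

*Study shape.* Ten participants (ages ~N(25.4, 3.7²), truncated to 18–65),
one validation session of 3–6 h with both devices, then 30 days of
test-only wear. Day-level compliance is a per-day Bernoulli with probability
`0.97 × 0.985^(d−1)` and daily wear windows of ~N(1150, 150²) minutes
clipped into the day, so valid-day counts decline over follow-up the way
real cohorts' do. Under the defaults this yields roughly 2,300–2,600 paired
validation epochs and ~200 valid person-days — sizes chosen so the full
suite simulates in seconds while leaving per-stratum counts (including
~150–200 MVPA epochs) large enough for stable Monte-Carlo checks.

*Determinism.* Every stream draws from a sub-seed derived arithmetically
from (master seed, participant index, stream id), so a fixed scenario is
bit-reproducible and adding participant 11 cannot perturb participants
1–10. The parameter-recovery tests exploit the retained ground truth:
subtracting the known slope term from each participant's differences
recovers \(\beta_{0i}\) within Monte-Carlo error, and zone-stratified biases
fall in the bands implied by the generator parameters.

*What passing tests do not show.* The generator's error model is additive,
smooth, and stationary. Real PPG failure is none of these: motion artifacts
produce spikes and cadence-locking, error depends on skin tone, tattoos and
strap tension, and dropout clusters rather than striking independently.
Agreement statistics verified here are verified as *computations*; nothing
in the synthetic cohort certifies how any physical device performs, and the
published coefficients that depend on a study's raw streams (an overall ICC,
an overall bias) are not quantities this package claims to reproduce.

## Numerical and degenerate-input choices

- ICC requires ≥ 3 epochs and nonzero total variance; perfect agreement
  returns ICC = 1 with a degenerate CI at 1. The implementation is checked
  against an independent brute-force sums-of-squares oracle to 1e-10 over
  hundreds of random small tables, and against an external reference
  implementation during development.
- Stratified analyses report undersized strata as explicitly insufficient
  instead of dropping them.
- Timestamps are naive local ISO-8601 (`YYYY-MM-DDTHH:MM:SS`); the study
  design is single-site, so timezone arithmetic is deliberately out of
  scope. Round trips through CSV are bit-exact, and duplicate timestamps
  are a hard error rather than a silent deduplication.
- Report bundles are pure functions of their inputs; reruns are
  byte-identical, which the test suite asserts at the file level.

## Parameter reference

| Parameter | Default | Units | Where |
|---|---|---|---|
| MVPA threshold | 0.50 of max HR | fraction | `zone_scheme()` |
| Max-HR intercept | 220 | bpm | `zone_scheme()` |
| Valid-day threshold | 600 | min/day | `daily_wear_summaries()` |
| Min. reference samples per minute | 1 (of 6) | samples | `pair_streams()` |
| Bias intercept (mean, SD) | −4, 1.3 | bpm | `device_error_model()` |
| Bias slope (mean, SD) | −0.15, 0.04 | bpm/bpm above rest | `device_error_model()` |
| Device noise (test, reference) | 3, 1.5 | bpm | `device_error_model()` |
| Dropout (test, reference) | 0.04/min, 0.02/10 s | probability | `device_error_model()` |
| HR time constant | 30 | s | `cohort_scenario()` |
| Follow-up | 30 | days | `cohort_scenario()` |
| Compliance decay | 0.015 | /day | `cohort_scenario()` |
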