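# wearhr

Validation analysis for wrist-worn optical heart-rate trackers compared
against a chest-strap reference under free-living conditions.

Consumer wrist trackers estimate pulse rate by photoplethysmography (PPG),
which is convenient for month-long wear but error-prone during movement;
chest straps measuring cardiac electrical activity are the accepted field
reference. Before tracker heart rates can be used for exercise prescription
or population activity surveillance, their agreement with a reference — and
their ability to detect minutes of moderate-to-vigorous physical activity
(MVPA) — has to be quantified on epoch-aligned, common-wear data. `wearhr`
implements that whole workflow for epidemiologists and exercise scientists
running such device-validation studies.

## What it computes

Streams are aligned on wall-clock 1-minute epochs: the tracker contributes
one reading per minute, the reference's 10-second readings are averaged
within the minute (zeros are the no-reading sentinel and never enter the
mean). A *common-wear* epoch has a nonzero reading on both devices; only
those are analysed, with the difference convention test − reference.

On the paired epochs, `hr_agreement()` fits:

- **ICC(A,1)** — single-measure, two-way, absolute-agreement intraclass
  correlation over subjects = epochs, raters = devices:

  `ICC(A,1) = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE))`

  with the F-based 95% CI (McGraw & Wong) and a strength label
  (weak < .5 ≤ moderate ≤ .7 < strong);
- **paired mean difference** with SE, 95% CI and paired-t p-value;
- **Bland–Altman** bias and limits of agreement (bias ± 1.96 SD of the
  differences);
- all of the above overall, stratified by age-based heart-rate zone
  (MVPA when HR ≥ 50% of 220 − age, assigned from the *reference* value)
  and by participant, plus decile box-plot summaries.

MVPA detection is summarized by a 2×2 reference-zone × test-zone table
(`build_contingency()`) and its sensitivity/specificity/PPV/NPV
(`diagnostic_metrics()`). Free-living wear is summarized per calendar day
(wear = nonzero minute; valid day = ≥ 600 worn minutes) into per-participant
zone-time tables and a cohort adherence curve.

Because raw device exports from such studies are rarely shareable, the
package includes a seeded synthetic cohort generator (`simulate_cohort()`):
semi-Markov activity bouts (nonwear/rest/light/MVPA), a mean-reverting true
heart-rate process with ~1-min lag, a faithful 10-s reference, and a 1-min
test device whose underestimate grows with intensity through
participant-specific bias intercepts and slopes — so every pipeline stage is
testable end to end with known ground truth.

## Worked example

```r
library(wearhr)

coh   <- simulate_cohort(cohort_scenario(seed = 1))   # 10 participants
pairs <- pool_pairs(lapply(coh$validation,
                           function(v) pair_streams(v$test, v$reference)))
fit <- hr_agreement(pairs)
print(fit)
```

```
Heart-rate device agreement on 2306 common-wear 1-min epochs
         stratum    n      ICC (95% CI) strength             diff (95% CI)     p
         overall 2306  0.94 (0.46-0.98)   strong    -5.74 (-5.93 to -5.55) <.001
        zone:low 2099  0.82 (0.04-0.94)   strong    -4.85 (-5.00 to -4.70) <.001
       zone:mvpa  207 0.74 (-0.05-0.93)   strong -14.73 (-15.50 to -13.97) <.001
 participant:P01  272  0.89 (0.11-0.97)   strong    -5.14 (-5.56 to -4.73) <.001
 ...
```

The tracker underestimates heart rate by about 5 bpm overall, and the
underestimate roughly triples in the MVPA zone — the intensity-dependent
error the generator builds in (bias intercept ≈ −4 bpm plus ≈ −0.15 bpm per
bpm above resting heart rate). The absolute-agreement ICC is penalized by
that systematic offset, and is weakest where the offset is largest.

```r
print(diagnostic_metrics(build_contingency(pairs)))
```

```
MVPA-detection diagnostics (positive class = reference MVPA)
  sensitivity   92.8% (192/207)
  specificity  100.0% (2099/2099)
  PPV          100.0% (192/192)
  NPV          99.29% (2099/2114)
```

```r
days <- do.call(rbind, lapply(Filter(Negate(is.null), coh$freeliving),
                              daily_wear_summaries))
freeliving_summary(days)[c(1, 11), ]
```

```
 participant valid days epochs noread % low % mvpa % MVPA min/day
         P01         21  30240     38.7  57.0    4.4           63
     overall        209 300960     37.5  58.3    4.2           61
```

Over ~200 valid person-days the cohort spends a low single-digit percentage
of epochs in the MVPA zone — roughly an hour a day.

`run_validation()` and `run_freeliving()` run the same analyses from CSV
inputs and write deterministic CSV/JSON report bundles; a thin command-line
wrapper with `simulate` / `validate` / `freeliving` subcommands is in
`inst/cli/wearhr.R`.

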