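---
title: "Methods: models, parameters and design choices in hdmonitor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in hdmonitor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`hdmonitor` implements the analysis chain of a smartphone/smartwatch remote
monitoring platform for Huntington disease (HD): eight self-administered
*active tests* (two cognitive, six motor) performed on a 4-week schedule,
each reduced to one predefined scalar feature per session, quality
controlled, median-aggregated over 2-week intervals, and validated
cross-sectionally with test-retest reliability, convergent validity and
known-groups comparisons. Since no participant-level study data are
available, the package carries its own synthetic-cohort generator that
reproduces the statistical structure the analysis assumes, giving every
downstream stage a recoverable ground truth.

## Feature definitions

Each test yields exactly one feature:

| Test            | Feature               | Units    | Definition |
|-----------------|-----------------------|----------|------------|
| digital SDMT    | `sdmt_correct`        | count    | responses whose digit matches the symbol-digit key |
| digital SWR     | `swr_correct`         | count    | longest common subsequence (LCS) of displayed and recognized word streams, capped at 60 |
| Speeded Tapping | `intertap_mean_ms`    | ms       | mean finger-in-air time: lift-off to next touch-down |
| Draw-A-Shape    | `spiral_speed_cv`     | unitless | coefficient of variation of instantaneous drawing speed along the spiral |
| Chorea, Balance | `sway_path`           | m/s²     | cumulative path length of the tri-axial acceleration trajectory, `sum(norm(a[i+1] - a[i]))` |
| U-Turn          | `turn_speed_median`   | rad/s    | median over detected turns of cumulative yaw angle / turn duration |
| Walking         | `step_freq_variance`  | Hz²      | variance of per-step frequencies `1/(t[i+1] - t[i])` |

Notes on the less obvious choices:

* **Sway path.** Summing acceleration *differences* makes constant offsets
  (gravity) cancel, so no orientation estimation or gravity removal is
  needed, and the result carries acceleration units, matching the
  conventional presentation of this feature. The path is not normalized by
  duration; the tests have fixed nominal lengths (30 s), so normalization
  would only rescale.
* **Intertap interval** is in-air time (up→down), not down→down cadence:
  choreatic movements are hypothesized to perturb the time the finger
  spends off the glass.
* **SWR matching via LCS.** The published definition says only "matching
  words". LCS tolerates skipped and misread words without double counting
  and reduces to exact-match counting when the recognizer output is clean.
* **Spiral CV units.** Published tables label spiral drawing speed
  variability in mm/s while the text defines it as a coefficient of
  variation, which is unitless. The CV definition is implemented; the
  discrepancy is surfaced here rather than resolved.
* **Turn detection.** Thresholds (yaw rate > 0.3 rad/s after a 0.5 s moving
  average, duration ≥ 0.5 s, cumulative angle ≥ π/2, ≥ 3 turns) are not
  published; they were chosen to detect deliberate 180° turns and reject
  postural noise, and are all arguments of `median_turn_speed()`. Region
  boundaries are refined on the *unsmoothed* rate: the moving average
  dilates the super-threshold region, and computing speed over the dilated
  region biases it low by roughly the ratio of smoothing window to turn
  duration (≈ 13% for a 2 s turn). Refinement removes that bias exactly for
  rectangular pulses.
* **Step detection.** Acceleration magnitude is band-passed to the
  locomotor band 0.5–3.5 Hz (zero-phase FFT masking), peaks ≥ 40% of the
  maximum with ≥ 0.25 s separation are steps; ≥ 10 steps are required.
* **Minimum-evidence gates** (≥ 2 taps, ≥ 3 turns, ≥ 10 steps, ≥ 3 trace
  points) are reported as QC failures (`qc_status = "fail"`), not errors: an
  unevaluable session is a data-quality outcome.
* **Resampling.** All IMU features are computed on a 50 Hz uniform grid
  (linear interpolation) because difference- and filter-based features
  require uniform sampling.

## Quality control

The platform's exact QC criteria were never published in full; the rule set
here is *reconstructed* and labelled as such in every report:

* placement: Walking, U-Turn and Balance sessions carried in the trouser
  pocket rather than the waist pouch always fail (the published analyses
  discarded these because pocket carriage skews step-frequency variance);
* duration: sensor recordings shorter than 90% of the nominal test length
  fail;
* completeness: a Draw-A-Shape attempt ends at the first finger lift, so
  traces covering < 50% of the reference spiral fail;
* the extraction gates above.

All thresholds are arguments of `qc_rules_default()` and surfaced in the
pipeline configuration. Fail rates are reported as `100 * excluded / total`
rounded at a report-level precision option (published rates mix 0, 1 and 2
decimals). A participant is *lost* for a test when neither 2-week interval
retains at least the aggregation minimum of passing observations.

## Aggregation

Reported values are medians per participant, feature and 2-week interval
(days 1–14 and 15–28, both closed; day 1 is device issuance). An interval is
missing when fewer than `n_min` passing observations exist: 1 for the weekly
SDMT/SWR, 3 for daily tests. Even-count medians use the midpoint convention.
Adherence is `100 * completed / scheduled` over the 4-week window, per study,
reported to 2 decimals.

## Validation statistics

* **Test-retest reliability** is the ICC between interval-1 and interval-2
  medians. The ICC form is fixed as two-way random effects, absolute
  agreement, single measurement — ICC(A,1) — because the same test is
  repeated under identical conditions; the published analysis cites a
  general ICC reference without naming a form, so the form is declared in
  the output (`$form`). CIs use the McGraw–Wong F-distribution bounds of the
  same model.
* **Convergent validity** correlates interval-1 medians with in-clinic
  scores. The method map defaults to Pearson for the cognitive tests and
  Speeded Tapping (pseudo-continuous scales on both sides) and Spearman
  otherwise (ordinal UHDRS items); an `auto` mode (Shapiro–Wilk at α = 0.05
  on both variables) exists but is off by default. CIs are Fisher-z, with
  the 1.06/(n−3) variance approximation for Spearman. No multiple-testing
  correction is applied anywhere; raw p-values and test counts are reported.
* **Known-groups validity** compares five groups — the three Digital-HD
  cohorts (control, premanifest, manifest) and the two manifest-only study
  populations (OLE, HD NHS) — on residuals of a mixed model
  `value ~ age + (1 | study)` fitted by REML, using a Kruskal–Wallis test
  and all 10 pairwise two-sided Mann–Whitney U tests.

  **Residual choice.** Residuals are *marginal* (observed minus the
  fixed-part age prediction) by default, not conditional. Two of the five
  groups coincide with whole studies, so subtracting BLUP study intercepts
  would absorb part of the very group differences under test; in null
  simulations this makes the Kruskal–Wallis test conservative (rejection
  rate ≈ 0.02 at α = 0.05), whereas marginal residuals keep it nominal. The
  random intercept still serves its purpose — estimating the age slope
  without confounding by study-level offsets. Conditional residuals remain
  available (`residual_type = "conditional"`).
* **Degenerate inputs.** ICC with zero total variance and correlations with
  constant input return flagged `undefined` results instead of errors;
  mixed-model failures fall back to a fixed-intercept age regression with a
  warning; residual vectors that are zero up to numerical noise yield
  Kruskal–Wallis H = 0 exactly.

## The synthetic cohort generator

A single latent severity s ∈ [0, 1] (truncated normal per cohort) drives
everything:

* **Clinical scores** are monotone functions of s plus noise, clamped to
  their scales, calibrated so cohort summaries land near the published
  baseline tables: TMS ≈ 100·s (controls ≈ 1–2, manifest ≈ 25–35), TFC
  pinned at 13 until s clears the premanifest range, in-clinic SDMT
  ≈ 62 − 90·s, SWR ≈ 101 − 85·s, per-hand chorea/finger-taps items and the
  balance score as rounded, clamped linear functions of s.
* **Cohort defaults**: control s ~ N(0.02, 0.02), premanifest N(0.06, 0.03),
  manifest N(0.28, 0.13), truncated to [0, 1]. Default study sizes are OLE
  46 manifest, HD NHS 94 manifest, Digital-HD 20/20/39.
* **Sensor signatures**: each test family has a baseline level, a linear
  severity slope, a stable per-participant trait weight and a session-noise
  weight (the last two on the log scale, keeping signals positive). The
  trait term creates between-subject variance — and hence non-trivial
  test-retest reliability — even within a homogeneous cohort; the session
  term creates within-subject variance. Signal models: band-limited
  (1–8 Hz) Gaussian sway noise superimposed on gravity (Chorea/Balance);
  six embedded ~π-radian rectangular yaw turns whose rate decreases with s
  (U-Turn); a quasi-periodic impulse train whose interval jitter SD grows
  with s (Walking); alternating touch events with in-air time mean/SD
  growing with s (Tapping); an Archimedean spiral traced at lognormal
  speeds with CV growing with s (Draw-A-Shape); response streams with rate
  and error probability driven by s (SDMT/SWR).
* **Walking cadence is constant** (0.5 s step interval) across severity.
  With a severity-dependent cadence the step rate drifts toward the band
  edge where interference between band-passed impulses compresses the
  measured interval variability, making the feature non-monotone in s. The
  feature of interest is interval *variability*, which the jitter term
  carries; gait slowing is deliberately not modelled.
* **Schedule**: daily tests on all 28 days (per-hand tests once per hand);
  SDMT and SWR weekly on days 1, 8, 15, 22 (a cadence choice — only weekly
  frequency is published). Completion is i.i.d. Bernoulli per scheduled
  test (study-level defaults 0.90/0.72/0.69); pocket carriage is i.i.d. per
  ambulatory session (defaults 0.30/0.22/0.18, chosen so placement
  exclusions land in the published 17–31% range). Placement is recorded
  metadata, not inferred from the signal.
* **Sampling**: all IMU streams are 50 Hz uniform, a typical wearable rate;
  no device rates or screen geometry were published, so these are generator
  parameters.

What the generator does *not* emulate: biomechanically realistic gait or
chorea dynamics, speech audio (the SWR input is the recognized-token
stream), learning/practice effects, diurnal or day-of-week structure in
adherence, device or placement effects on the signal itself, and
missing-not-at-random dropout. A green end-to-end test therefore
establishes that the pipeline's accounting, statistics and effect
directions are correct under the stated generative model — not that the
features are clinically valid on real recordings.

## Numerical choices

* Band-pass filtering is zero-phase FFT bin masking; adequate for short,
  roughly stationary test recordings, not a general filter.
* Peak picking is greedy by height with a minimum-separation constraint;
  ties are broken by sample order.
* Deterministic sub-seeds are derived from one master seed and integer keys
  (participant index, test, hand, day) via a 31-bit linear-congruential
  hash, so any session can be regenerated in isolation and runs are
  byte-identical under a fixed seed.
* Interval medians use `stats::median`; pairs with a missing interval are
  dropped pairwise per analysis.

## Known limitations

* The QC rule set is a reconstruction; published per-stratum fail rates can
  be reproduced arithmetically but not re-derived from raw criteria.
* The headline reliability and validity coefficients of the source studies
  were computed on unavailable participant data; the package recovers their
  *structure* (signs, orderings, nominal error rates, constructed ICCs) on
  synthetic cohorts instead.
* The Chorea dual-task (counting backward) stream, passive monitoring,
  patient-reported outcomes and smartwatch-channel features are out of
  scope; the smartphone signals suffice for all defined features.
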