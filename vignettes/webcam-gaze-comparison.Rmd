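---
title: "Comparing lab and webcam visual-world gaze pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing lab and webcam visual-world gaze pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazepipe)
```

## The problem

Visual-world studies of sentence comprehension present a spoken sentence
together with two pictures (a target depicting the correct interpretation
and a foil depicting the reverse) and track where participants look as the
sentence unfolds. The proportion of gaze on the target, time-locked to the
*disambiguation point* — the word at which the correct interpretation
becomes determinable — indexes comprehension as it happens. This is
especially informative in aphasia, where persons with aphasia (PWA) show
delayed and attenuated target fixation for non-canonical structures such as
passives.

Webcam eye tracking (browser-based gaze estimation from consumer cameras)
promises to widen access to such studies, but differs from laboratory
infrared tracking in three ways that matter for time-course analyses:

* **sampling rate** — a lab tracker delivers a gaze estimate every ~2.3 ms
  on average, a webcam pipeline roughly every 49 ms, with very irregular
  spacing (interval SD larger than the mean in both cases, dramatically so
  on the web);
* **spatial precision** — webcam estimates are noisy, so analysis regions
  must be large;
* **temporal lag** — webcam gaze estimates arrive systematically late,
  on the order of several hundred milliseconds.

`gazepipe` implements the full analysis pipeline for a two-modality
(lab + web), two-group (control + PWA) sentence–picture matching study —
area-of-interest (AOI) assignment, trimming, binning, per-bin proportion
models, and a group-difference lag analysis — together with a synthetic
study generator, so that every stage can be verified by parameter recovery
at desk scale.

## Trial timeline and design

A trial starts with a 300 ms fixation cross, then shows the two pictures
for a 700 ms apprehension phase before the audio begins; the disambiguation
point therefore always falls after 1000 ms on the trial clock. The design
contains 65 trials: 15 actives, 15 passives, 15 locatives, and 20
intransitive fillers (10 declaratives, 10 wh-questions). The target appears
on the left in half the trials of each type (odd counts split 8/7, with the
majority side randomized). For actives and passives the disambiguation
point is the post-verbal noun onset; for locatives, the first preposition.
Per-item disambiguation times are not fixed constants of the design: the
generator draws them uniformly from configurable per-structure windows
(defaults 1600–2400 ms for actives/passives, 1500–2300 ms for locatives),
which stands in for natural item-to-item variation in audio timing. These
windows are stipulations of the simulator, not estimates of any particular
stimulus set.

## AOI geometry

Lab acquisition software defines AOIs around the pictures at acquisition
time and exports labeled samples, so lab streams enter the pipeline in
*label mode* and pass through unchanged. Webcam samples arrive as raw x/y
pixel coordinates and are classified post hoc against
viewport-proportional rectangles: the left box spans 15%–45% of the
viewport width, the right box 55%–85%, and both start at 22.5% of the
viewport height and are half the viewport high (ending at 72.5%). On a
1920 × 1080 screen the left box is x ∈ [288, 864), y ∈ [243, 783). Boxes
are deliberately generous because webcam spatial precision is poor.

Two conventions are ours to fix because no standard exists:

* **boundary ties** use half-open intervals `[start, end)` on both axes, so
  every sample maps to exactly one of target / foil / neither;
* **coordinates** are screen pixels with the origin top-left and y
  increasing downward, the convention of both acquisition stacks.

Samples falling in neither box are labeled `none`, retained in the data
store, and excluded from proportion denominators (a switch restores them to
the denominator for sensitivity analyses, since with very noisy tracking
the choice is not innocent).

## Trimming and binning

Three cleaning rules are applied, each exactly once (provenance flags make
a second application an error, because the 2-SD rule is not idempotent):

1. **timestamp trim** — within each trial, samples more than two sample
   standard deviations (n − 1 denominator) from the trial's mean timestamp
   are removed, two-sided; trials with fewer than 3 samples or zero SD pass
   through;
2. **accuracy/RT trim** — inaccurate trials are dropped, then, within each
   participant × modality session, trials with RT more than 2 SD from the
   session mean; accuracy models use the untrimmed table;
3. **RT transform** — reaction times (measured from trial onset) are
   square-root transformed before linear modeling.

Gaze samples are then aggregated into half-open 100-ms bins over the
0–12,000 ms trial window (bins 0–100 through 11,900–12,000; 120 bins), and
the per-trial, per-bin proportion of target samples out of target + foil
samples is the dependent variable. Bins with no countable samples are
absent from the output rather than zero-filled. Binning is done on the
absolute trial clock; `rel_bin` (bin minus the disambiguation bin) is
carried along for alignment and display.

## Models

Three model families mirror the stages of a typical analysis:

* **accuracy** — binomial mixed logistic regression of correctness on
  structure type and modality with participant and item random intercepts,
  fitted for the PWA group only (controls respond at ceiling, leaving
  nothing to model); on non-convergence the fit falls back to fixed-effects
  logistic with a warning;
* **reaction time** — Gaussian mixed model of √RT on
  group × structure × modality with participant and item intercepts
  (Satterthwaite degrees of freedom via `lmerTest`), with marginal and
  conditional variance-explained summaries;
* **gaze proportions** — a weighted *quasibinomial* logit regression with
  bin as a categorical factor interacting with group / structure /
  modality. Random-effect structures are deliberately absent from this
  family: per-trial-bin proportions are plentiful and strongly
  overdispersed, and the dispersion parameter absorbs that.

The quasibinomial fitter is implemented in the package (iteratively
reweighted least squares) rather than delegated, because it is the piece
the rest of the inference hangs on:

* weights are the per-cell binomial totals (target + foil counts);
* the dispersion is estimated as Pearson χ²/df on the original rows, and
  all standard errors are scaled by its square root;
* the IRLS solves on covariate-aggregated cells — rows with identical
  covariates enter the binomial likelihood only through their weighted
  totals, so the maximizer is unchanged while a 120-bin omnibus model
  solves on a few hundred rows instead of hundreds of thousands;
* rank deficiency (an empty design cell for a requested interaction) is an
  error naming the offending columns, not a silently dropped coefficient.

Unit tests hold this fitter to an independent oracle: direct numerical
maximization of the binomial log-likelihood (to 10⁻⁶ on ≤ 200-row
fixtures), the closed-form saturated solution for a two-cell design, and
`stats::glm(family = quasibinomial)` as a cross-check.

**Per-bin contrasts.** From the omnibus fit, the contrast engine builds
equal-weight marginal means at every bin and tests link-scale differences
(e.g. PWA − control, or the difference of that difference between web and
lab) with dispersion-scaled normal/t statistics. Equal weighting of the
averaged-over factors is our choice; frequency weighting is available
through `marginal_contrast()`. Contiguous significant bins of one sign are
summarized as windows (onset bin, offset bin), which is how divergence
onsets are conventionally narrated. No multiplicity correction is applied
across bins by default — per-bin reporting at α = 0.05 is the field's
convention for these displays — but `adjust = "bonferroni"` or `"BH"` is a
one-argument switch. One bin-factor omnibus model (rather than 120
separate per-bin fits) is used throughout; with the saturated bin
interactions the two routes coincide in their point estimates.

**Effect sizes.** The coefficient tables carry an approximate standardized
effect size computed from the test statistic, d = 2t/√df. It is labeled
approximate deliberately: it is a monotone transform of the statistic, not
an independently estimated quantity.

## The Δgaze lag analysis

To compare the *timing* of group effects across tracking modalities, the
pipeline computes Δgaze: for each bin × structure × modality cell, the
control group's mean target proportion minus the PWA group's. Trials are
weighted equally within the group mean by default (a
participant-means-first switch exists, since either convention is
defensible). Δgaze is modeled by ordinary linear regression on bin number
× modality — no random effects, as the series is already an average — and
the bin × web interaction tests whether group differences persist later on
the web. Because consecutive bins of an averaged series are serially
correlated, the p-values of this regression should be read descriptively;
the lag estimators below do not depend on them.

The web-vs-lab lag itself is estimated three ways:

* **peak**: difference of the argmax bins of the two series (ties go to
  the earliest bin);
* **dip**: the same with argmin;
* **xcorr**: the lag maximizing the normalized cross-correlation over a
  ±20-bin search window — an addition beyond the peak/dip comparison, and
  the most robust of the three on noisy series.

Peaks and dips are located on the raw per-bin series by default; a centered
3-bin moving average is available (`smooth = TRUE`) but off, so that the
estimator's input is exactly the series the user sees. Missing bins are
linearly interpolated inside `estimate_lag()` only — `compute_delta()`
never invents cells.

## The synthetic-study generator

`sim_config()` + `simulate_study()` generate complete studies — trial
tables, viewports, and gaze streams for every participant in both
modalities — with the statistical structure the analysis assumes:

* **sampling clocks**: inter-sample intervals are lognormal,
  moment-matched to means of 2.3 ms (SD 13.91) in the lab and 49 ms
  (SD 162.2) on the web. A lognormal is used for both modalities because
  both interval distributions have SD greater than the mean, i.e. are
  strongly right-skewed, and the lognormal is the simplest strictly
  positive law matching those two moments exactly;
* **gaze time course**: the probability that a sample lands on the target
  is 0.5 until `disambiguation + group onset delay (+ web lag)`, then
  follows a logistic ramp `0.5 + (a − 0.5)(2/(1 + e^{−r(t−t₀)}) − 1)`
  rising to a group × structure asymptote `a`. A sigmoid ramp is the
  natural minimal form for the empirical S-shaped rise of target fixation;
  all of its parameters are exposed, none hard-coded. An optional late
  decay pulls the PWA curve back toward 0.5 after a configurable time
  (off by default);
* **defaults** (per group): onset delay 150 ms (control) vs 900 ms (PWA);
  ramp rate 0.004/ms vs 0.0015/ms; asymptotes ~0.85–0.90 (control) vs
  0.70–0.80 (PWA). These produce control divergence within a few hundred
  ms of disambiguation and a PWA deficit emerging over the following one
  to two seconds, the qualitative shape such studies report;
* **web lag**: a single configurable shift (default 600 ms, the middle of
  the few-hundred-ms range webcam pipelines exhibit) added to the web
  ramp onset;
* **behavior**: accuracy is Bernoulli from group × structure logits
  (controls near ceiling at logit 4.6; PWA actives 1.8, passives 0.8,
  locatives 1.2) plus participant- and item-level normal shifts (SD 0.5
  and 0.3 logits); RT is lognormal with additive log-scale shifts for
  group (+0.22 for PWA), structure, and modality (−0.12 on the web,
  reflecting shorter web RTs), plus participant (SD 0.15) and item
  (SD 0.05) effects;
* **noise and loss**: web coordinates are the AOI center plus Gaussian
  noise (SD 80 px; lab label streams use 15 px nominally); a per-modality
  dropout probability (2% lab, 10% web) sends samples outside both AOIs;
* **determinism**: one master seed; the design and item effects, and each
  participant's streams, run on sub-seeds drawn from the master stream, so
  identical configurations are byte-identical and participant streams do
  not shift when group sizes change.

**What the generator does not emulate** — and hence what passing
recovery tests do and do not show: saccade kinematics and fixation
structure (samples are conditionally independent given the ramp, so there
is no oculomotor autocorrelation), blinks and track loss bursts,
calibration drift, head movement, item-specific picture biases, and
participant-level variation in the *gaze* parameters (only behavioral
parameters get random effects). Tests passing on this generator show the
pipeline recovers what it assumes; they cannot certify performance on real
webcam data, where the lag itself may drift within a session.

## Monte-Carlo problem sizes

The statistical guarantees are checked by simulation at sizes chosen to
make the checks sharp but repeatable on a single CPU:

* type-I calibration of per-bin group contrasts: 200 replicates of a
  null study (all asymptotes 0.5) with 6 + 6 participants, web modality
  only — the modality is irrelevant under the null and the web stream is
  the cheaper one — compared against the nominal 5% within two Monte-Carlo
  standard errors;
* lag recovery: injected web lags of 300/500/800 ms, 25 full-scale
  (16 + 16 participants, both modalities) replicates split across the
  three lags, recovered by cross-correlation to within one bin (100 ms)
  on average per lag;
* effect recovery: the PWA passive accuracy deficit over 50 behavioral
  replicates at 16 PWA, and the transient gaze deficit window (equal
  asymptotes, delayed/slower PWA ramp) over 6 full-scale replicates,
  scored by Jaccard overlap (≥ 0.5) between the detected significant
  window and the generator's own half-maximum deficit window.

## Known limitations

* The Δgaze regression inherits serial correlation across bins; its
  standard errors are anticonservative and are reported as-is by design.
* The quasibinomial omnibus model treats bins as exchangeable categories;
  no smoothness across time is exploited (a growth-curve or GAM route
  would, but is out of scope).
* Peak/dip lag estimates on noisy series can land on neighboring bins;
  the cross-correlation estimator is the one held to recovery guarantees.
* Lab AOIs drawn in acquisition software are not reconstructed; lab
  exports must arrive pre-labeled.
* The effect-size column is a df-scaled transform of the test statistic,
  not a standalone estimate.
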