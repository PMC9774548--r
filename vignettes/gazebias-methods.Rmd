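---
title: "Measuring spontaneous gaze preference: methods behind gazebias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spontaneous gaze preference: methods behind gazebias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The paradigm

`gazebias` analyses *spontaneous gaze preference* experiments: two animal
pictures are shown side by side on a 1920 x 1080 screen for 5 s while a
remote eye tracker samples binocular gaze position at roughly 60 Hz, with a
2 s central fixation cross between slides. No task is given; the relative
amount of looking at each stimulus measures *attentional bias*. The design
the package targets contrasts threatening chelicerates (spiders, scorpions)
with a non-threatening control insect (short-horned grasshoppers) in two
populations (Somali and Czech participants) and both genders. Each of the
18 stimulus pairs appears twice — once in its original left/right
arrangement and once horizontally mirrored — so side preferences cancel,
giving 36 slides per participant.

The pipeline goes: gaze samples → fixations → per-AOI trial metrics →
curation (exclusions, mirror-pair averaging with observation weights) →
weighted mixed-effects models of total fixation metrics and of
within-slide differences.

## Fixation detection

The detector implements a *lead-sample dispersion rule* on the
mean-binocular stream. The first sample is the lead of the first candidate
fixation; every subsequent sample joins the current fixation iff its
Euclidean distance to the *current lead* is at most 37 px (one degree of
visual angle on this display; the threshold is inclusive, "no farther
than"). A sample that leaves the fixation always becomes the new lead. A
run is a fixation only if it has at least 3 consecutive samples. Fixation
duration is defined as `n_samples * 1000 / 60` ms, so the minimal fixation
lasts 50 ms; the alternative (last-minus-first timestamp) would give
33.3 ms for 3 samples and is deliberately not used, keeping the sample
count and the duration consistent.

Two points where the rule needed sharpening:

* **Distance reference.** Classical I-DT limits the pairwise spread of a
  window; this rule is *lead-referenced* — membership is judged only
  against the run's first sample. The two disagree on streams that drift
  monotonically; tests pin the lead-referenced behaviour against an
  independent literal-rule oracle, exhaustively over all streams of length
  ≤ 12 on a 3-point alphabet.
* **Missing samples.** "Consecutive" means consecutive *retained* samples.
  Blinks and track loss are dropped upstream; a single missing sample
  (time gap of two nominal intervals) does not break a run, while a longer
  gap closes it and the next sample becomes a lead. The tolerance of two
  sampling intervals is the package's own choice and is configurable
  (`detector_config(max_gap_ms=)`).
* **Discarded sub-threshold runs** are not revisited: detection is a
  greedy single pass, which makes it order-linear and deterministic.

## AOI metrics

Three rectangular, pairwise-disjoint areas of interest are used: the left
stimulus half, the right stimulus half, and the fixation cross. Published
AOI definitions rarely come with pixel geometry, so the package declares
an explicit default — left `[0, 860) x [0, 1080)`, right `[1060, 1920) x
[0, 1080)`, cross `[860, 1060) x [440, 640)` — and makes it fully
configurable (`aoi_set()`); overlap is rejected at configuration time.

A fixation is assigned to **every AOI containing at least one of its
member samples**, and accrues its *full* duration to each. This
whole-fixation accrual is what allows combined AOI fixation time to exceed
the 5 s slide when gaze hugs a border — exactly the pathology that
curation criterion (a) screens for; per-sample time splitting would make
that criterion vacuous. Exported per trial and AOI: number of fixations,
total fixation time, and the durations of the first, second and third
fixation assigned to that AOI (ordinal within the AOI), plus the trial's
retained sample count (approximately 300).

## Curation

A trial is excluded iff

* (a) combined fixation time over all AOIs exceeds 5500 ms (strict
  inequality, "over 5500 ms"), or
* (b) the left or the right AOI received zero fixations (the cross AOI is
  never consulted by this rule).

Both reasons are reported per trial. Kept trials are then collapsed over
mirror pairs: using the schedule's left/right image categories, side-keyed
metrics are re-keyed to *animal* categories (a pair and its mirror show the
same animals on swapped sides), and each participant x base-pair
observation is the mean of its two slides (weight 1.0) or the single
surviving slide's values (weight 0.5). The weight feeds the residual
variance model below. Before collapsing, `position_effect_check()` fits
the per-slide focal-side difference on focal position x pair type with a
participant random intercept, the pre-check that justifies averaging.

Bookkeeping quantities (total measurements, exclusions per criterion,
full-pair versus half-weight counts, the full-pair subset used by the
count model) are reported separately and never reconciled into a single
denominator, because they answer different questions.

## The statistical models

All models share a participant random intercept. For gaussian responses
(total fixation time; the within-slide differences) the residual variance
follows

$$\mathrm{Var}(\varepsilon_{ij}) \;=\; \sigma^2\,
  \frac{\delta^2_{\mathrm{nat}(i)}}{w_{ij}},$$

a per-nationality multiplier (`nlme::varIdent`, reference level fixed at
1) combined with inverse observation-weight scaling (`nlme::varFixed`).
Fitting uses `nlme::lme`; reported estimates come from REML fits.

* `fit_total_metric_model()`: total fixation time per animal, fixed
  effects `animal * nationality * gender`.
* `fit_count_model()`: total fixation counts are Poisson; no weight-based
  variance structure exists for `lme4::glmer`, so — rather than discard
  the weights silently — the model analyses only full mirror pairs and
  uses the *integer sum* of the two slides' counts as response (log link,
  Laplace approximation).
* `fit_difference_model()`: within-slide differences (first-named animal
  minus second: spider−grasshopper, scorpion−grasshopper,
  scorpion−spider), fixed effects `pair_type * nationality * gender`,
  gaussian with the variance structure above. Positive estimates mean
  more attention on the first-named (predicted more threatening) animal.

**Model reduction** (`reduce_model()`) is backward from the highest-order
interaction: a term may be dropped only when it is droppable under
marginality, its likelihood-ratio test (between ML fits) is
non-significant at α = 0.05, *and* removal does not worsen AIC; among
eligible terms the least significant goes first, and the final gaussian
model is refitted by REML. The α for the gate is a package decision (none
is standard); both the per-step tests and the full-versus-final likelihood
ratio are recorded in the fit object. Note that for a 2-df interaction the
AIC condition binds before the 5% level, so a truly null term is retained
about 14% of the time — a property of the joint rule, not a bug.

**Inference.** Marginal (Type-III-style) F tests come from
`anova.lme(type = "marginal")` with nlme's containment denominator
degrees of freedom — the df convention of the fitting engine itself;
Satterthwaite approximations are not available for `lme` fits with
combined variance structures. Tukey post hoc contrasts of a factor within
strata use `emmeans`. Cell predictions tested against zero
(`test_differences_against_zero()`) are computed directly from the fixed
effects and their covariance with containment-style df (the smallest df
among the coefficients a cell uses); a unit test verifies the estimates
and standard errors agree with `emmeans` to numerical precision.

## The synthetic-data generator

Because raw gaze data of this kind are not machine-readably available, the
package ships a generator whose defaults *are* the study conditions it
emulates: 132 valid participants (24/41 Somali women/men, 35/32 Czech
women/men), 36 slides of 5 s at 60 Hz, and per-cell expected differences
equal to the magnitudes characteristic of the paradigm (for fixation time,
e.g. 618.20 ms for Somali men viewing scorpion–spider pairs, 0.66 ms —
effectively null — for Czech women on the same pairs; analogous tables for
counts).

A trial is built as: an initial 400 ms dwell on the cross, then
alternating fixations and 3-sample saccade gaps until the 300-sample grid
is full. Each fixation chooses the threat side with probability $p$ and
draws a log-normal duration (median 250 ms, `sdlog` 0.4; multiplied by $m$
on the threat side), rounded to samples with a 3-sample floor; samples
scatter around a uniformly placed AOI-interior anchor with 4 px Gaussian
jitter. Per-sample track loss (2%) blanks both eyes, and 1% of samples
lose one random eye, exercising the single-eye fallback. Optional
injections plant curation violations: criterion-(a) trials anchor every
fixation on the stimulus/cross border so its duration double-counts;
criterion-(b) trials direct all fixations to one side. Injection rates
default to the curated rates of the emulated cohort (19/4752 and
346/4752).

### Calibration

$(p, m)$ follow from the per-trial targets $(\tau, c)$ — time and count
difference — by an occupancy argument: with $n$ fixations of mean realized
durations $\mu_t$ (threat) and $\mu_c$ (control) and gap $g$ filling time
$T$,

$$n(p\mu_t + (1-p)\mu_c + g) = T,\qquad
  n(p\mu_t - (1-p)\mu_c) = \tau,\qquad n(2p-1) = c,$$

which solves in closed form for $n$, $p$, $\mu_t$; $m$ follows by
inverting the (numerically tabulated) map from duration multiplier to mean
realized duration after rounding. The closed form ignores duration
rounding, end-of-trial truncation, clamping of extreme targets, and — most
importantly — the fact that downstream curation removes one-sided trials
and thereby truncates the realized difference distribution. All of these
are absorbed empirically by `calibrate_generator()`: a noise-free pre-run
per design cell measures the intrinsic fixation-process SD
(`sigma0`, about 1000–1100 ms under the defaults) and first-order bias;
trial-level Gaussian noise is then sized and iterated (damped fixed-point,
measuring on curation-surviving trials) so that the *total* residual SD of
the time difference equals `resid_sd_ms * nat_resid_mult[nationality]`,
and a final large pre-run pins the additive mean corrections. Calibration
is deterministic (own internal seed), runs once per configuration
(1–2 minutes), and is cached inside the config object.

Two consequences worth knowing:

* `resid_sd_ms` cannot go below the intrinsic process SD; the generator
  warns and floors the extra noise at zero. The default (1600 ms) is of
  the order implied by the cell confidence intervals typical of published
  studies in this paradigm.
* The participant-level shift (`participant_sd_ms`, default 300 ms)
  applies to the time difference only; count differences vary through the
  fixation process itself.

The exported ground truth (cell means, participant effects, per-nationality
total residual SDs, injected trials, per-trial latent fixation plans)
makes recovery scoring (`score_recovery()`) possible without touching the
generator internals.

### What the generator does and does not emulate

It reproduces the sampling geometry, fixation/saccade alternation, track
loss, side-bias structure, heteroscedasticity across populations and the
curation pathologies. It does **not** attempt realistic saccade
kinematics, pupilometry, image-content salience, drift or calibration
error of real eye trackers. Passing recovery tests therefore shows the
*analysis pipeline* is consistent and well-calibrated under the stated
noise model — not that the substantive findings would replicate on new
human data.

## Numerical and design choices

* Time is ms from slide onset (inputs in seconds are converted on read);
  coordinates are pixels, origin top-left.
* Mean-binocular gaze falls back to the single available eye rather than
  dropping the sample.
* "Interlaced with at least two completely different pairs" is formalized
  as positional separation ≥ 3 between a slide and its mirror mate;
  schedules come from seeded rejection sampling (bounded at 10,000
  tries), and the reversed-order set is the exact reversal (separation is
  symmetric).
* Stimulus colour matching is modelled as a label; the canonical image
  set's colour groups are laid out so a perfect cross-category matching
  exists, and unpairable sets fall back to arbitrary within-type pairing
  with a warning.
* The third pair type is labelled `scorpion-spider` (scorpion first) so
  that factor labels and the difference sign convention coincide.
* Metrics tables are written with 17 significant digits so the CSV
  round-trips doubles exactly.
* Simulation studies in the test-suite run at reduced cohort sizes
  (2–4 participants per design cell, 100–200 replicate cohorts; the
  law-of-large-numbers check uses one 500-participant cohort) — sizes
  chosen so every check retains adequate simulation precision.

## Known limitations

* Containment df (from nlme) differ from Satterthwaite/Kenward–Roger df;
  p-values near the threshold can differ across engines, which is one
  reason numeric equality with any published table is not promised even
  in principle.
* The Poisson count model ignores the half-weight observations entirely
  (by design, following the full-pair subset approach) and can be
  underdispersed on synthetic data, making its Wald tests conservative.
* The greedy detector never revisits discarded sub-threshold samples; a
  re-testing variant would merge some short runs differently. The greedy
  reading is the one the duration arithmetic (50 ms minimum) supports.
* Extreme per-trial difference targets saturate (a 5 s slide bounds the
  realizable difference); the calibration compensates in mean and SD but
  the realized noise distribution has slightly lighter tails than
  Gaussian there.
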