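# gazebias

Attentional-bias analysis for paired-stimulus eye-tracking experiments.

`gazebias` is an R implementation of the complete analysis pipeline for
*spontaneous gaze preference* studies: two animal stimuli (here,
threatening chelicerates — spiders and scorpions — versus control
grasshoppers) are shown side by side for 5 s on a 1920 × 1080 display
while binocular gaze is sampled at ~60 Hz, and the relative amount of
looking quantifies attentional bias across populations (Somali / Czech)
and genders. The package is aimed at researchers running or re-analysing
such experiments, and at methodologists who want a fully simulable
test-bed for the statistical machinery.

It provides:

* **Fixation detection** by the lead-sample dispersion rule: a fixation is
  a maximal run of ≥ 3 consecutive retained samples each within 37 px
  (1° visual angle, inclusive) of the run's *lead* sample; duration is
  `n_samples × 1000/60` ms, so the minimal fixation is 50 ms.
* **AOI metrics** per trial (left stimulus, right stimulus, fixation
  cross): fixation counts, total fixation time, first/second/third
  fixation durations, with whole-fixation accrual to every AOI touched.
* **Curation**: exclusion of trials with combined AOI time > 5500 ms (a)
  or zero fixations on a stimulus side (b); mirror-pair averaging re-keyed
  by animal with observation weights (1.0 full pair, 0.5 lone slide).
* **Models**: linear mixed models with participant random intercepts and
  the residual variance structure
  Var(ε) = σ² δ²<sub>nat</sub> / w (per-nationality multiplier ×
  inverse observation weight, via `nlme`); Poisson GLMMs for fixation
  counts on full-pair sums (`lme4`); backward reduction by LRT + AIC;
  Tukey post hoc contrasts (`emmeans`); per-cell difference estimates
  tested against zero.
* **A calibrated synthetic gaze generator** that emulates the full study
  (sampling, fixation/saccade structure, track loss, planted attentional
  biases, heteroscedasticity, curation pathologies) with exported ground
  truth for parameter-recovery studies.

## Worked example

Simulate a small cohort and run the pipeline end to end:

```r
library(gazebias)

cfg <- generator_config(participant_counts = data.frame(
  nationality = c("Somali", "Somali", "Czech", "Czech"),
  gender      = c("woman", "man", "woman", "man"),
  n           = c(4, 4, 4, 4)))
cfg <- calibrate_generator(cfg)   # deterministic, ~1-2 min, once per config

cohort   <- simulate_cohort(cfg, seed = 7)
analysis <- run_gaze_pipeline(cohort, reduce = FALSE)
analysis
```

```
<gazebias_analysis>
  trials: 576 of 576 expected; excluded a=2, b=42; kept 532
  curated observations: 286 (246 full pairs, 40 half weight)
  position effect: p = 0.0607 (interaction p = 0.00853)
  model total_time: fixation_time_ms ~ animal * nationality * gender
  model count: n_fix_sum ~ animal * nationality * gender
  model diff_time: d_fix_time_ms ~ pair_type * nationality * gender
  model diff_count: d_fix_count ~ pair_type * nationality * gender
```

The trial count is participants × slides (16 × 36); exclusions follow the
two curation rules, and each kept mirror pair collapses into one weighted
observation. The difference-model cell estimates (first-named animal minus
second, in ms) are tested against zero:

```r
head(analysis$zero_tests$diff_time, 3)
```

```
            pair_type nationality gender estimate    SE  df lower.CL upper.CL t.ratio   p.value
   spider-grasshopper      Somali  woman    29.71 207.7 262   -379.2    438.6  0.1431 8.864e-01
 scorpion-grasshopper      Somali  woman  1070.45 212.3 262    652.3   1488.6  5.0410 8.649e-07
      scorpion-spider      Somali  woman   738.89 210.0 262    325.4   1152.3  3.5189 5.108e-04
```

Positive estimates mean more looking at the first-named (more threatening)
animal; at this deliberately tiny cohort size only the strongest planted
biases reach significance, and the position pre-check can flag at the 5%
level by chance, as any alpha-level test will on one cohort in twenty. With the default 132-participant configuration the
estimates centre on the generator's planted cell means (e.g. 618.2 ms for
Somali men viewing scorpion–spider pairs).

A command-line wrapper over the same functions ships in
`inst/cli/gazebias.R` (subcommands `simulate`, `detect`, `curate`,
`model`, `run`).

## Package layout

```
R/                 implementation (config, IO, schedule, detection, AOI
                   metrics, curation, models, simulator, pipeline)
tests/testthat/    unit, property and acceptance tests with independent
                   brute-force oracles
scripts/           acceptance script
vignettes/         methods vignette (model, assumptions, calibration,
                   design decisions, limitations)
inst/cli/          command-line wrapper
```
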