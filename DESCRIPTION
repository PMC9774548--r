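Package: gazebias
Title: Attentional-Bias Analysis for Paired-Stimulus Eye-Tracking Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for spontaneous gaze preference experiments in
    which two animal stimuli (threatening chelicerates versus control insects)
    are shown side by side while binocular gaze is sampled at 60 Hz. Provides
    lead-sample dispersion-based fixation detection, area-of-interest (AOI)
    gaze metrics, trial curation with mirror-pair averaging and observation
    weights, weighted linear mixed models with a per-nationality
    heteroscedastic variance structure, Poisson mixed models for fixation
    counts, backward model reduction by likelihood-ratio test and AIC, Tukey
    post hoc contrasts, and a calibrated synthetic gaze-stream generator for
    end-to-end validation and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nlme,
    lme4,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
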