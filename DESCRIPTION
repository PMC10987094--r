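Package: ssvepcue
Title: Simulation and Analysis of Frequency-Tagged EEG in Cued Contrast
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how probabilistic expectation cues shape the
    encoding of sensory evidence during contrast discrimination. Provides a
    generator for two-alternative forced-choice trial schedules with
    reciprocal-contrast gratings, evidence pulses and a trial-replacement
    mechanism; adaptive calibration procedures (transformed up-down
    staircases and a grid-based QUEST titration) exercised against simulated
    psychometric observers; a synthetic multichannel EEG generator with
    frequency-tagged steady-state visual evoked potentials (SSVEP), mu-beta
    and alpha oscillations, 1/f background noise and blink artifacts; a
    preprocessing chain (detrending, zero-phase low-pass filtering, robust
    bad-channel detection, spherical-spline interpolation, average
    re-referencing, epoching, threshold artifact rejection, current source
    density transformation); short-time Fourier amplitude extraction with
    neighbour-bin SSVEP normalisation and data-driven electrode selection;
    and a linear mixed-model battery with Satterthwaite degrees of freedom
    for behavioural, sensory and motor-preparation effects across task
    exposure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
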