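---
title: "Methods: simulating and analysing cued contrast discrimination with frequency-tagged EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing cued contrast discrimination with frequency-tagged EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

When observers receive a probabilistic cue about the likely outcome of a
perceptual decision, their reaction times and choices shift toward the
cued alternative. The open question is where in the processing chain the
prior acts: purely in the decision machinery (a shift in the starting
point of evidence accumulation, visible as biased motor preparation), or
also in the encoding of the sensory evidence itself. A contrast
discrimination task with two overlaid orthogonal gratings makes this
separable with EEG: phase-reversing the gratings at different rates
(20 and 25 Hz) drives a separable steady-state visual evoked potential
(SSVEP) for each, whose amplitude scales with that grating's contrast.
The difference between the target- and non-target-driven SSVEPs — the
*marginal SSVEP* — indexes the encoded evidence, while the hemispheric
lateralisation of mu-beta (MB, 8–30 Hz) activity over motor cortex
indexes motor preparation, and occipito-parietal alpha (8–14 Hz)
desynchronisation indexes stimulus engagement.

`ssvepcue` implements this entire study as a tested, simulated pipeline:
the task-design generator, the adaptive calibration procedures, a
synthetic EEG forward model with known ground truth, the preprocessing
and spectral-extraction chain, and the trial-level mixed-model battery.
Because every stage runs against synthetic data whose generating
parameters are known, every downstream claim — "the pipeline recovers an
invalid-cue reduction of the marginal SSVEP that emerges with task
exposure" — can be stated as a falsifiable test.

## The task model

A trial is: 1000 ms fixation; a 400 ms fade-in during which both
gratings rise monotonically from 0% to 50% contrast (the cue appears
during this phase); an 800 ms baseline with both gratings at 50%; then
2000 ms of evidence in which the target steps to `50 + m` percent and
the non-target to `50 - m` percent, where `m` is the calibrated marginal
contrast. Contrast divergences are always reciprocal, so total contrast
is constant. The response deadline is 1800 ms; correct responses earn
+50 points and errors −25.

Cues are valid, invalid, or neutral in a 4:1:1 ratio, making directional
cues 80% predictive. Sessions also embed 150 ms evidence *pulses* —
reverse (evidence flips sign), gap (evidence removed), positive
(evidence doubled) — at one of five onsets (180–500 ms in 80 ms steps);
the 16 pulse conditions (15 pulse cells plus no-pulse) are equally
represented. On a 60/40 trial a reverse pulse therefore changes total
contrast by 40 percentage points, which is the package's first
acceptance check. Early responses trigger a replacement mechanism:
responses before evidence onset replicate the trial at the end of its
block; responses before a pulse feed an extra end-of-session block in
sets of three (one immutable replica plus two mutable alternatives).

Design choices here: the cue composition is allocated session-wide and
dealt evenly over pulse cells, so that even a 16-trial session contains
all three cue conditions with the 16 cells exactly once; timing is
quantised to the 10 ms frames of a 100 Hz display; the gratings' spatial
starting phase alternates by a half cycle across trials and is carried
into the EEG generator's carrier phase.

## Calibration

Each simulated session titrates the contrast differential to 70%
accuracy against a simulated observer: a 2AFC Weibull psychometric
function parameterised directly by its 70%-correct differential
(guess rate 0.5, slope 3.5, lapse 0.02 by default), plus a "flicker
bias" parameter expressing the tendency to perceive the
higher-frequency grating at lower contrast.

Three adaptive stages are implemented:

* **Two interleaved one-up-two-down staircases** (terminate after four
  reversals or 50 trials), which converge on the level yielding
  `sqrt(0.5) ≈ 70.7%` correct.
* **A one-up-one-down staircase** (four reversals or 60 trials) that
  finds the contrast boost to the 25 Hz grating at which the observer is
  indifferent (50% choice rate) — the flicker-bias compensation.
* **A grid QUEST**: a posterior over the threshold on a log grid from
  0.5 to 100 pp, Weibull likelihood, lognormal prior centred at 20 pp,
  60 trials placed at the running posterior mean. If the estimate
  implies a target contrast above 65% (differential above 30 pp), the
  insufficient-practice flag is raised. A 30-trial verification block
  follows; accuracy off 70% by 5 points or more forces a rerun after
  adjusting by the QUEST margin of error.

The staircase step schedule is not specified by the task description, so
it is a design choice with a hard requirement: the procedures must reach
their theoretical convergence points under the four-reversal
termination. A fixed 8 pp step biased the one-up-two-down estimate
badly upward (the descent from 100% differential is slow relative to the
step-halving), so the estimation staircases use an initial step of
16 pp, halving at each reversal with a 1 pp floor, and exclude the first
two (approach-transient) reversals from the converged-level estimate;
with this schedule the long-run median accuracy at the converged level
is 70.0% against the 70.7% theoretical point. The one-up-one-down
staircase starts at a zero boost (already near its convergence point)
and keeps all reversals. Four-reversal runs are intrinsically noisy
(interquartile range of per-run accuracy roughly 58–82%), so
convergence is always assessed as a median over many seeded runs, and
the convergence property is asserted at differentials of 20–25 pp — the
range the task's titration actually produces; below ~10 pp the 1 pp
step floor is coarse relative to the threshold.

## The synthetic EEG forward model

`simulate_trial_eeg()` builds a 512 Hz, 35-scalp-channel (plus two
VEOG) trial spanning −1700 to 2000 ms around evidence onset, as a sum
of:

* **SSVEP carriers**: for each grating, a sinusoid at its tag frequency
  whose instantaneous amplitude is `ssvep_gain × contrast(t)`
  (default 0.05 µV per percent contrast), focused over occipital
  channels with a Gaussian spatial profile peaked at Oz. Harmonics are
  omitted — the pipeline reads only the fundamental. The cue's effect is
  injected as a gain on the contrast *differential* (default 1 for all
  cues), optionally ramped linearly from no effect at the start of
  testing to its nominal value at the end.
* **Mu-beta**: a fixed set of 8–30 Hz sinusoids (placed away from the
  tag bins) over each central region (C3/C4), whose amplitude drops by
  `mb_lateralization` (1 µV) contralateral to the cued response from cue
  onset, and by `mb_response_desync` (1.5 µV) contralateral to the
  executed response over the 400 ms preceding it.
* **Alpha**: a 10 Hz oscillation over occipito-parietal midline sites
  with amplitude set per cue condition (default 3 µV cued, 2.4 µV
  neutral — neutral trials show stronger desynchronisation, i.e.
  greater engagement).
* **1/f background noise** (3 µV RMS, spectral exponent 1) on every
  channel, and **Poisson blinks** (300 µV raised-cosine events) on the
  VEOG pair with frontal propagation.

The noise level is a synthetic choice — no SNR is given for the real
recordings — set so that single-trial recovery of the marginal-SSVEP
sign succeeds on ≥95% of trials at default gain, which mirrors the
qualitative reliability of the real signal. What the generator does
*not* emulate: harmonic SSVEP structure, eye movements beyond blinks,
non-stationary noise, volume-conducted source mixtures beyond the
Gaussian topographies, or realistic head geometry. Passing tests
therefore demonstrate the pipeline's correctness and sensitivity under a
plausible forward model, not performance guarantees on real recordings.

Behaviour is drawn from a base 70% accuracy shifted on the logit scale
by cue (+0.184 valid, −0.219 invalid — the study's accuracy contrasts
read as logit-scale quantities, since no scale is stated) and a shifted
lognormal RT with additive cue shifts (correct: −0.043 s valid,
+0.085 s invalid; error: +0.084 s valid, −0.047 s invalid).

For the replicate-hungry statistical suites (type-I calibration, power)
a measures-level generator (`simulate_measures_table()`) draws per-trial
measure rows directly from the forward model's summary distribution,
with subject random intercepts on each measure family. The full EEG
path is exercised end to end at small n in the pipeline tests; the
measures-level route is what makes 100–500 replicate studies feasible
on one CPU in minutes.

## Preprocessing

Fixed order: per-channel linear detrend and zero-phase FIR low-pass
(Hamming, order 128, −6 dB at 40 Hz) → bad-channel detection →
spherical-spline interpolation → average reference → epoching with
baseline correction → threshold artifact rejection → current source
density (CSD).

Bad channels are those whose median-across-epochs log variance has a
robust z score (median/MAD across channels) beyond ±3.5 — the median
across epochs means a single artifactual epoch cannot condemn a channel,
while persistently noisy or dead channels are caught in both
directions. Interpolation and CSD use the classic spherical-spline
G/H-matrix formulation (order m = 4, 50 Legendre terms, CSD
regularisation λ = 1e−5); the spline reproduces constants exactly, the
CSD is linear and maps uniform fields to zero, and these are tested
properties, not assumptions.

Epochs: cue-locked −1700:500 ms and evidence-locked −400:2000 ms (both
relative to evidence onset; baselines −1400:−1200 and −600:−400 ms),
response-locked −600:400 ms relative to the response, cut from the
surviving evidence-locked data. All windows are half-open
`[start, end)`; the evidence-locked baseline window lies before the
epoch span, so baseline means are computed from the continuous data
before cutting. A trial is rejected when the VEOG difference exceeds
250 µV or any scalp channel exceeds 100 µV anywhere in the epoch;
rejection runs separately per epoch type, so the cue- and
evidence-locked analyses have independent keep-sets.

## Spectral extraction

Amplitudes come from a short-time Fourier transform with a rectangular
taper, 400 ms windows (360 ms for alpha) moved in 50 ms steps, each
estimate mapped to its window midpoint on the 50 ms grid anchored at the
alignment event. At 512 Hz a 400 ms window is 204.8 samples; it is
realised as 205 samples, so the bin spacing is 512/205 = 2.4976 Hz and
the 20/25 Hz tags sit within 0.025 Hz of bin centres — the worst-case
noise-free amplitude error from this quantisation is about 0.2%, and
exact-bin sinusoids are recovered to machine precision (the DFT-oracle
equivalence and Parseval checks in the test suite are exact).

The SSVEP at a tag bin is normalised by subtracting the mean of the two
bins on each side of it, skipping both tag bins — an estimate of the
local broadband floor that is unbiased under white noise (also a tested
property). The mean (not the sum) of the neighbours is subtracted; the
sum is available via `reduce = "sum"`. Mu-beta is the mean amplitude
over the 8–30 Hz bins *excluding* the two tag bins, so tagged visual
activity cannot leak into the motor measure; alpha is the mean over
8–14 Hz with the 360 ms window. Channels are averaged before the
transform by default (`combine = "after"` averages amplitude spectra
instead).

Electrode selection is data-driven as in the study design: SSVEP
electrodes are the top two occipital candidates ranked by mean
target-minus-non-target normalised amplitude in 200:1800 ms; MB
electrodes are the top two per hemisphere by the rank-sum of (1) the
ipsilateral-minus-contralateral amplitude at response and (2) the
negated pre-response slope; ties break by candidate order and a
no-signal situation is flagged low-confidence. The three
occipito-parietal midline alpha electrodes (Pz, POz, Oz) are fixed.

Analysis windows: marginal SSVEP during evidence in 680:975 ms (after
the last possible pulse offset at 650 ms); baseline-phase SSVEP and MB
lateralisation in −752:−214/−215 ms (both printed forms select the same
midpoints on the 50 ms grid); alpha in −410:−70 ms; pre-/post-response
marginal SSVEP in −200:−50 and 50:200 ms.

## Statistical battery

All models are trial-level with a single subject random intercept and no
other random effects. Identity-link models are linear mixed models with
Satterthwaite-approximated denominator degrees of freedom for Type-III
F tests; binary accuracy models are logistic mixed models with Wald
chi-square tests reported as F on their numerator df (denominator
df ∞). Pairwise condition contrasts are uncorrected, matching the
study's reporting; no other multiplicity correction is applied,
deliberately. If the random-intercept variance is estimated at zero the
model is refit with a fixed intercept and labelled (`df_method =
"residual"`). Task exposure is the per-subject chronological quintile
(equal counts ±1, remainder to the earliest bins), entering models as a
centred linear covariate (bin − 3) so main effects are evaluated at
mid-exposure rather than extrapolated to bin zero.

The battery (registered in `inst/analyses.yaml`) comprises: the full RT
model with the cue-validity × accuracy interaction; separate correct-
and error-RT models (validity × exposure); the logistic accuracy model;
the five SSVEP models (validity during evidence; anticipatory
cued-vs-neutral at baseline; target/non-target × cue; validity ×
exposure; pre/post-response difference); the SSVEP-to-behaviour link
models on trials slower than 680 ms; and the pre-evidence MB and alpha
models with valid and invalid collapsed to "cued". Behavioural and
evidence-locked SSVEP models carry pulse type and tag frequency as
control fixed effects; the RT inclusion rule is >100 ms generally,
>680 ms for the SSVEP-link models, and none for the pre-evidence MB and
alpha analyses.

## Problem sizes, calibration and power

The suites run at sizes chosen for a single desktop CPU:

* Type-I calibration: 500 replicate null datasets of 8 subjects × 60
  trials, one battery model fit per replicate (cycled); the empirical
  false-positive rate at α = 0.05 must lie in [0.03, 0.07].
* Exposure-ramp recovery: 100 replicates of 12 subjects × 1536 trials
  with the invalid-cue differential gain ramping from 1 to 0.8 across
  testing; the validity × exposure interaction (with a negative
  invalid slope) must be detected in ≥80% of replicates. The trial
  count matters: the interaction contrast carries the variance of the
  reference-condition slope as well, so at 768 trials per subject the
  joint F has only ~50% power; 1536 is still under a third of the real
  study's ~5750 trials per subject.
* Static invalid-gain recovery (gain 0.9, 40 subjects × 144 trials,
  100 replicates) and behaviour-delta recovery run in the module tests.

## Degenerate inputs and numerical choices

A constant response yields an all-zero effect table rather than an
error; factors that collapse to one level in a subset (e.g. tiny
verification runs) are dropped from the formula; model fits that fail
outright fall back to fixed-intercept fits with a warning. The QUEST
posterior is renormalised each trial and errors out if mass concentrates
at a grid bound. Staircase levels clip to [0, 100]. Epoch cutting
requires a sample within one sample period of each window edge, else the
trial is dropped with a log entry. Spline fits use an augmented system
with a zero-sum constraint; interpolation uses a near-zero ridge
(1e−8) for numerical stability.

## Known limitations

The forward model's topographies are Gaussian blobs, so the
data-driven electrode selection is easier than on real scalp maps; the
bad-channel detector will flag strongly signal-bearing channels in
synthetic data with homogeneous noise (harmless here, since the spline
interpolation preserves the smeared signal, but worth knowing); the
logistic models' Wald tests are asymptotic, not Satterthwaite; and the
measures-level generator assumes Gaussian residuals for the amplitude
measures, which real CSD amplitudes (non-negative, right-skewed) only
approximate. None of the reported properties depend on OSF data: this
package reproduces the *design* numbers and the pipeline's behaviour
under a known forward model, not the study's fitted coefficients.
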