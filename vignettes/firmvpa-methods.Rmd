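---
title: "Decoding voluntary imagery before the decision: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding voluntary imagery before the decision: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firmvpa)
```

## The scientific problem

In a free-decision imagery task, a participant chooses at their own pace
which of two gratings to imagine and presses a button the moment the
decision is made, then imagines the chosen grating for 10 s and rates its
vividness from 1 to 4. The analytical question is whether the *content*
(which grating) and the *strength* (vividness) of the upcoming imagery
can be decoded from multi-voxel BOLD patterns recorded *before* the
button press — and, if so, how early, whether the predictive patterns are
perceptual in nature, and whether apparent pre-decision information is an
artefact of the previous trial.

`firmvpa` implements the full analysis chain for this question:

1. **FIR beta series** — high-pass filtered (128-s discrete-cosine
   filter) ordinary least squares with a 14th-order finite-impulse-
   response basis anchored at the press, one 2-s bin per TR spanning
   −13 s to +15 s (bins are labelled by their start time, −13 … +13, so
   14 bins cover 28 s: this resolves the apparent arithmetic of a
   "−13 to +13 s" window). Each run × grating × bin yields one beta
   pattern, the sample unit of all decoding.
2. **Time-resolved decoding** — leave-one-run-out linear SVM (libsvm,
   cost 1, no feature scaling: betas are already expressed relative to
   the run mean) per bin, averaged over folds, tested against 50 %
   chance across subjects with a one-tailed one-sample t-test.
3. **Perception→imagery generalization** — a classifier trained once on
   perception block betas (15-s flickering-grating blocks, boxcar
   regressors, one beta per block) and tested on imagery betas per bin,
   or on pooled −10..0 s / 0..10 s windows for sensitivity.
4. **Searchlight mapping** — 3-voxel-radius spherical searchlight,
   8-mm-FWHM Gaussian smoothing of accuracy maps, voxel-wise group
   t-test at p < 0.001 and cluster-extent inference at p < 0.05 by
   sign-flip max-cluster-size permutation (26-connectivity).
5. **Permutation inference** — 1000 within-run label shuffles re-run
   through the whole GLM + decoding pipeline; percentile confidence
   bands; a family-wise error test on the *count* of significant time
   bins; and null-bias diagnostics (mean, skewness, kurtosis,
   normality).
6. **Controls** — the N−1 ("spillover") relabelling that asks whether
   pre-press decodability is explained by the previous trial, and the
   univariate ROI-mean contrast that asks whether decoding reflects mere
   activation differences.
7. **Auxiliary analyses** — phase-encoded retinotopy (FFT phase and SNR
   at the 0.033 Hz stimulation frequency, SNR ≥ 2 threshold) and the
   behavioural rivalry-priming experiment that validates the reported
   imagery onset (raw priming, within-participant z-scores, definitional
   one-way ANOVA, catch-trial reliability, d′).

Because no imaging data are deposited for this paradigm, the package
ships a synthetic-data generator with complete ground truth; every stage
of the pipeline is validated against it.

## The generator

`simulate_imagery_run()` packs self-paced trials into a run: 10 s lead-in
fixation, then per trial a 2-s prompt, a gamma-distributed decision time
(shape 2, mean 5.48 s, right-truncated at 20 s — the reported mean and
cap; the distribution's shape is not reported and is a configuration
knob, not a claim), the press, 10 s imagery, 3.7 s of report prompts and
10 s rest. The prompt time is chosen so the expected trial span is about
31 s, which reproduces the reported ~9.2 trials per 5-minute run. Labels
follow a switch policy (default switch probability 0.586, the empirical
rate); the first label is a fair coin, so label balance converges to
50/50.

The injected signal has three parts, all HRF-convolved (canonical
double-gamma: peak 6 s, undershoot 16 s, ratio 6 — the analysis side
never assumes this shape):

* the **chosen grating's pattern** (unit-norm, zero spatial mean, so the
  signal is purely multivariate and invisible to the univariate
  control), active from `onset_lag` before the press (default −11 s, the
  regime of interest) through the imagery period, scaled per trial by
  `amplitude × max(0, 1 + amplitude_sd·z)`;
* a **label-independent strength component** along a direction orthogonal
  to both grating patterns, active during the pre-press buildup and
  scaled by the same trial amplitude. Vividness ratings are a monotone
  binning of a latent mixture of this amplitude (weight
  `vividness_coupling`) and noise, so future-vividness decoding has a
  linearly decodable target exactly when the coupling is positive. A
  purely label-specific amplitude modulation would make "high vs low"
  radially rather than linearly separable, which no linear classifier
  could learn; modelling strength as an overall engagement direction is
  both decodable and biologically the more natural reading. Its scale
  (`strength_fraction`, default 4) is calibrated once so that
  full-coupling vividness decoding lands near 60 %, the strength-
  decoding regime reported for V1;
* an optional **carryover component**: a fraction of the previous
  trial's pattern persisting from the end of its signal epoch until the
  next press, the ground truth that the N−1 control is designed to
  detect.

Noise is white Gaussian innovations through an AR(1) filter (default
innovation SD 5.5, coefficient 0.3) plus a 256-s sinusoidal drift with
random per-voxel phase (period chosen slower than the 128-s cutoff so
the high-pass filter must remove it). The noise scale is calibrated —
once — so that bin-wise content decoding at `amplitude = 1` peaks in the
mid-60s percent range, the time-resolved regime the ROI analyses of
this paradigm report. Four scanner-equilibration volumes plus extra AR
burn-in are simulated and discarded; second 0 of every event table is
the first retained volume.

What the generator does **not** emulate: physiological (cardiac/
respiratory) noise, motion, spatial autocorrelation of noise, subject-
specific HRF variability, and anatomical geometry (subjects share a
grid; no normalisation step is needed or modelled). Passing tests
therefore demonstrate the correctness and calibration of the analysis
machinery on data satisfying its assumptions, not robustness to every
artefact of real acquisitions.

## Numerical and design choices

* **Bin membership** is left-closed: a volume belongs to bin *j* if its
  acquisition onset lies in `[start_j, start_j + 2)` anchored at the
  press. Presses are not snapped to the volume grid.
* **Filtering order**: data and design are filtered identically before
  OLS (residual-forming-matrix equivalence). No prewhitening — AR(1)
  robustness is covered by tests, not modelling.
* **Inestimable betas are `NA`, never zero**: a run lacking one label
  yields missing betas for that label and the affected cross-validation
  folds are skipped with a warning.
* **Permutation caching**: label shuffles only re-assign per-trial FIR
  columns to label columns, so filtered cross-products are cached per
  run and each null iteration reduces to a small solve. The cache is
  proven output-identical to a full refit in the test suite.
* **SVM conventions**: cost 1 (exposed), no scaling; a decision value of
  exactly 0 predicts the alphabetically first class (measure-zero).
  Class imbalance within folds is left as-is, except where the analysis
  demands balance (vividness split), where the larger training class is
  subsampled with a seeded RNG.
* **Add-one permutation p-values** (never exactly zero) for both the
  counting FWER test and cluster inference.
* **Vividness split**: ratings 1–2 vs 3–4 (the acquisition-scale rule);
  a mean-split alternative is exposed as an option without endorsing
  either as canonical.
* **Per-trial window betas** (−10..0 s) are estimated alongside nuisance
  boxcars for the 0..10 s and 10..15 s epochs of every trial, so that
  response from the imagery period and its offset decay is not absorbed
  into the run baseline — without these, baseline contamination
  correlates with a run's class composition and biases leave-one-run-out
  accuracy *below* chance.
* **Onset estimation**: the earliest bin opening a run of ≥ 2
  consecutive pointwise-significant bins. The consecutive-bin guard
  protects against isolated false positives among the many pre-press
  bins (with 7 pre-press bins at α = 0.05, the chance of at least one
  isolated false positive is ~30 %).
* **Cluster inference** replaces Gaussian-random-field cluster
  correction with sign-flip max-cluster-size permutation: same
  error-rate target, fully self-contained, and exactly testable by
  simulation. Connectivity is 26-neighbour. Spatial normalisation is out
  of scope (synthetic subjects share a grid); searchlight spheres are
  clipped to the analysis mask rather than zero-padded.
* **Retinotopy SNR** divides the stimulation-frequency amplitude by the
  mean amplitude of all other non-DC frequencies excluding a one-bin
  guard band around the stimulation bin; the denominator convention is
  isolated in one function because published descriptions rarely state
  it.

## The validation experiments

Each acceptance property is an experiment in `R/validate.R`, run by both
the test suite and `scripts/acceptance.R`. Problem sizes are the
package's choices, set to keep each study in the minutes range on one
CPU while leaving the Monte-Carlo error well inside the asserted
tolerances:

* **Null calibration**: 8 no-signal subjects × 5 runs on a 12³ grid,
  200 within-run label-shuffle iterations through the full pipeline.
  Checks the ensemble grand mean (50 ± 1 pp) and the pointwise t-test's
  type-I rate (0.05 ± 0.01) across all iteration × bin cells.
* **Onset recovery**: groups of 14 subjects × 6 runs, lags swept over
  the bin starts −11 … −1 s; the earliest-significant-bin estimate is
  scored against the true lag at ± 1 bin.
* **Generalization specificity**: 50 simulated subjects per overlap
  level (0, 0.5, 1) with 3 perception and 5 imagery runs each.
* **Spillover validity**: 28 subjects per carryover level (0 and 0.8),
  with the trial's own pattern starting at the press so that any
  pre-press N−1 decodability can only reflect carryover; the subject
  statistic is the N−1 accuracy averaged over the pre-press bins
  (−13..−1 s), the span of the lingering pattern. The group is larger
  than for the other studies because the hemodynamic tail of the
  previous trial's own response partially counteracts the carryover
  evidence, inflating between-subject variance.
* **Counting-test FWER**: 500 global-null experiments with 200-iteration
  ensembles, simulated at the accuracy level with leave-one-run-out
  granularity (running 100 000 full GLM+SVM pipelines is not a sensible
  use of a calibration study; the counting rule is exercised exactly as
  the pipeline applies it).
* **Retinotopy**: 1000 responsive voxels (unit amplitude — the strong
  periodic responses typical of phase-encoded mapping) plus 200 silent
  voxels in AR(1) noise; mean absolute circular phase error of
  voxels passing the SNR ≥ 2 threshold, and the silent-voxel exclusion
  rate.
* **Future vividness**: 16 subjects per coupling level (0, 0.5, 1),
  per-trial pre-press window betas, balanced-subsampled leave-one-run-out
  decoding of high vs low vividness.

## A known limitation: hemodynamic detection latency

The onset-recovery study deserves a frank note. The generator injects a
*sustained* discriminative pattern whose BOLD signature is the
convolution of a boxcar with the HRF; the response therefore rises like
the *cumulative* HRF, reaching roughly 20 % of its plateau within 2–4 s
of the true onset and half the plateau only after ~5–6 s. An onset
estimate defined as the earliest statistically significant bin is a
threshold-crossing detector, and at any realistic group size the
threshold is crossed two to three bins (4–6 s) after the true lag: we
measure a stable delay of about +6 s at 14–20 subjects per group. This
is not an implementation defect but a property of threshold-based onset
estimation on hemodynamically low-passed signals; detecting the first
post-onset bin at the calibrated signal-to-noise level would require
groups of several hundred subjects. Consumers of the onset estimate
should read it as "information was decodable from at least this early",
biased late by the hemodynamic rise — the same caveat applies to any
empirical onset claim derived from BOLD decoding curves. The
acceptance suite states the ± 1-bin recovery property anyway and reports
its measured success rate rather than weakening the check; the mean
recovery delay is also reported by the acceptance script.

## Reading the outputs

`run_experiment()` chains the stages for a configured group and writes a
tidy bundle: per-subject decoding curves, pointwise significance, the
univariate contrast, the permutation percentile band, the counting-test
verdict and a hash manifest (outputs are staged and only moved into
place on success). All randomness descends from the single master seed,
so re-running a configuration reproduces the bundle bit for bit.

```{r driver, eval = FALSE}
cfg <- default_config()
cfg$n_subjects <- 8L
cfg$stats$n_permutations <- 500L
res <- run_experiment(cfg, out_dir = "results/demo")
res$onset_seconds     # earliest consecutive-significant bin
res$fwer$p            # familywise p for the count of significant bins
```
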