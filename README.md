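# firmvpa

Time-resolved decoding of the content and strength of voluntary visual
imagery from fMRI, for researchers studying the pre-volitional origins
of thought. In a free-decision imagery task a participant chooses which
of two gratings to imagine and presses a button at the moment of
decision; `firmvpa` asks whether multi-voxel BOLD patterns *before* the
press already predict what will be imagined and how vividly.

The analysis core is a beta-series MVPA pipeline:

* **FIR deconvolution.** BOLD series are high-pass filtered with a
  128-s discrete-cosine filter and fit by OLS with a 14th-order
  finite-impulse-response basis anchored at the press — bin *j* covers
  `[-13 + 2(j-1), -13 + 2j)` seconds, one bin per TR (2 s), spanning the
  28 s around the decision. Each run × grating × bin yields one beta
  pattern β ∈ R^V.
* **Decoding.** Leave-one-run-out linear SVM (libsvm, C = 1, no
  scaling) per time bin; group inference by one-tailed one-sample
  t-tests of accuracy against 50 %. Cross-classification trains on
  perception-block betas and tests on imagery betas (no folding —
  training and test runs are disjoint), probing whether predictive
  patterns are perceptual in nature.
* **Inference.** Within-run label-shuffle permutation nulls re-run
  through the whole GLM + decoding chain (with an exact cross-product
  cache), percentile confidence bands, a family-wise error test on the
  count of significant time bins, and null-bias diagnostics. Searchlight
  maps (radius-3 sphere, 8-mm smoothing) get cluster-extent inference by
  sign-flip max-cluster-size permutation (voxel p < 0.001, cluster
  p < 0.05).
* **Controls.** The N−1 "spillover" relabelling (is pre-press
  decodability just the previous trial?) and a univariate ROI-mean
  contrast (is it just activation level?).
* **Auxiliaries.** Phase-encoded retinotopy (FFT phase and SNR at
  0.033 Hz, SNR ≥ 2 threshold) and the binocular-rivalry priming
  analysis used to validate self-reported imagery onsets (raw priming,
  within-participant z-scores, one-way ANOVA, catch-trial reliability,
  d′).

Because raw data for this paradigm are not publicly deposited, the
package includes a synthetic BOLD generator
(`simulate_imagery_run()`, `simulate_perception_run()`,
`simulate_retinotopy_run()`, `simulate_rivalry_session()`) with complete
ground truth — self-paced decision times, HRF-convolved multivoxel
patterns emerging at a configurable lag before the press, pattern
carryover, perception–imagery overlap and amplitude-coupled vividness —
so that every stage of the pipeline is verifiable by simulation. See the
methods vignette (`vignettes/firmvpa-methods.Rmd`) for the models,
parameter defaults and validation-study designs.

## Worked example

Simulate a small group whose imagery patterns switch on 11 s before the
press, decode every time bin, and run the permutation inference:

```r
library(firmvpa)
cfg <- default_config()
cfg$n_subjects <- 6L
cfg$n_runs <- 5L
cfg$stats$n_permutations <- 200L
res <- run_experiment(cfg)
res$significance
```

```
   bin_time accuracy     p
1       -13   46.667 0.820
2       -11   35.000 0.920
3        -9   51.667 0.370
4        -7   50.000 0.500
5        -5   50.000 0.500
6        -3   75.000 0.011
7        -1   65.000 0.015
8         1   70.000 0.013
9         3   53.333 0.230
10        5   75.000 0.032
11        7   75.000 0.011
12        9   53.333 0.290
13       11   61.667 0.079
14       13   58.333 0.110
```

```r
res$onset_seconds          # -3: earliest run of consecutive significant bins
res$fwer$observed_count    # 5 significant bins ...
res$fwer$p                 # ... familywise p = 0.005 against the null count
res$null_bias$grand_mean   # 50.17: the permutation null sits at chance
```

Decoding rises above chance before the press (−3 s and later at this
small group size; larger groups detect earlier bins), the count of five
significant bins is far beyond what label-shuffled nulls produce
(familywise p ≈ 0.005), and the null ensemble is centred on 50 % —
the three readouts a real study of this design reports. Note the onset
estimate lags the true −11 s injection: a sustained pattern's BOLD
signature rises like the cumulative HRF, so threshold-crossing onsets
are systematically late (discussed in the vignette).

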