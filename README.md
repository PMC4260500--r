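# wmload

Cross-task decoding of working-memory load (WML) from oscillatory EEG, with a
synthetic-session generator for end-to-end testing.

## The problem

Adaptive learning environments need a continuous, unobtrusive readout of how
hard a learner's working memory is working. A passive brain-computer
interface can provide one: rising WML expresses itself in the EEG as a power
increase in the theta band (4–7 Hz) over frontal-midline electrodes and a
power decrease in the alpha band (8–13 Hz) over parietal sites. The catch is
that classifiers must be *trained* on tasks free of perceptual-motor
confounds (controlled working-memory tasks) and then *applied* to realistic
learning material (algebra word problems) — cross-task classification — and
that realistic learning material can only be presented simple-to-complex, so
slow EEG drifts are confounded with difficulty unless the features cancel
them.

`wmload` implements that full pipeline for researchers in neuroadaptive
instruction and passive BCI methodology:

- **Schedulers** for a within-task design (alternating 45-s study windows on
  angle theorems vs comic strips) and four cross-task paradigms — numerical
  n-back (digits every 2000 ms, no digit 7), reading span (2/4/6
  letters per span, 500-ms fixation, 1000-ms letter), and subtraction /
  fraction word problems with three difficulty levels and exactly four
  numerical givens each.
- **A forward model** generating multichannel EEG for any schedule: per
  channel `x(t) = g(t) [w_θ A_θ (1 + k_t W(t)) osc_θ(t) + w_α A_α (1 − k_a W(t)) osc_α(t) + noise] + artifacts`,
  with latent load `W(t)` driven by the schedule, slow multiplicative drift
  `g(t)`, 1/f background, blink and keypress-EMG artifacts, and 7-point
  load ratings coupled to `W`.
- **Preprocessing**: least-squares EOG regression; per-trial activation
  (`I_a`) and resting (`I_r`) intervals that never come within 125 ms of any
  keypress; 15-s epoch segmentation of artifact-free study windows.
- **Spectral features**: Burg autoregressive spectra (lattice recursion in
  C++), evaluated at 4–13 Hz, combined into
  `%ERD/ERS = (P_a − P_r)/P_r × 100` on a 10 electrode × 10 frequency grid
  (F3, Fz, F4, FC1, FC2, CP1, CP2, P3, Pz, P4) — the ratio form cancels
  multiplicative drift.
- **Labeling & calibration**: classes from each subject's mean
  working-memory-task rating (low/high WML), 2-of-3 difficulty-level
  selection for cross-task comparability, train-statistics z-scoring.
- **Classification**: SVM with RBF kernel (inner grid search, stratified
  CV), per-trial cross-task evaluation, permutation significance
  (`p = (1 + #{perm ≥ obs}) / (B + 1)`), cohort reports.

## Worked example

Simulate one subject's cross-task session, decode it, and test significance
(reduced session sizes and 200 Hz sampling keep this quick):

```r
library(wmload)
cfg <- study2_config(n_nback_trials = 24, n_spans = c(5, 3, 2), n_problems = 6)
res <- run_study2(seed = 42, config = cfg, model = forward_model(rate = 200), B = 199)
res
#> <wml_study2> subject S01 | cutoff 3.5
#>         task n_test accuracy p_value
#>  subtraction     12    83.3%   0.065
#>     fraction     12    91.7%   0.070
res$selection
#> <wml_selection> cutoff 3.5 | kept levels:
#>   fraction      1, 2
#>   nback         2, 3
#>   reading_span  2, 3
#>   subtraction   2, 3
```

Reading this: the SVM was trained on the pooled n-back + reading-span trials
of the two retained difficulty levels per task, with low/high WML classes cut
at this subject's mean working-memory rating (3.5). Applied trial-by-trial to
the held-out algebra tasks it classified 83% of subtraction and 92% of
fraction trials correctly; the permutation p-values are limited by the small
per-task trial count (12). The fraction task's hardest level was dropped by
the calibration step as too hard relative to the other tasks, the other
tasks' easiest levels as too easy.

The within-task mode decodes material type from raw alpha power in 15-s
epochs:

```r
run_study1(seed = 7, model = forward_model(rate = 200))
#> <wml_study1> subject S01: CV accuracy 100.0% (comic=45, theorem=45 epochs)
```

Cohorts: `study2_cohort(n_subjects = 16, seed = 1, ...)` returns a per-cell
table with mean accuracy and the significant/total count;
`signature_sweep()` traces decoding power against the strength of the
simulated theta/alpha signature.

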