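---
title: "Decoding working-memory load from oscillatory EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding working-memory load from oscillatory EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmload)
```

## Scope

`wmload` implements a passive brain-computer-interface pipeline that decodes
working-memory load (WML) from single-trial oscillatory EEG, in two modes:

* **within-task**: classify which of two alternating instructional materials
  (hard angle theorems vs easy comic strips) a learner is studying, from raw
  alpha band power in 15-s epochs, with stratified 10-fold cross-validation;
* **cross-task**: train on two controlled working-memory tasks (numerical
  n-back, reading span) and classify, trial by trial, the subjectively easy
  vs hard trials of two algebra word-problem tasks never seen in training.

Because no recorded EEG ships with the package, a synthetic-session
generator produces data with exactly the structure the analysis assumes.
Every stage is therefore testable end to end; what that does and does not
establish about real EEG is discussed at the end.

## The neural signature and the forward model

The pipeline rests on the best-replicated oscillatory correlate of WML:
frontal-midline theta power (4–7 Hz) grows with load
(event-related synchronization, ERS), parietal-occipital alpha power
(8–13 Hz) shrinks with load (event-related desynchronization, ERD). The
generator encodes that signature as two narrowband sources mixed into a
10-channel montage (F3, Fz, F4, FC1, FC2, CP1, CP2, P3, Pz, P4, plus VEOG
and HEOG):

$$x_c(t) = g(t)\,\big[\,w_{\theta c} A_\theta (1 + k_t W(t))\,\mathrm{osc}_\theta(t)
  + w_{\alpha c} A_\alpha (1 - k_a W(t))\,\mathrm{osc}_\alpha(t) + n_c(t)\big] + a_c(t)$$

* $W(t) \in [0,1]$ is the latent load: piecewise constant at the trial's
  value during the trial's *engagement span* (digit processing, letter
  encoding, problem solving) and at a low rest level (default 0.1)
  elsewhere. Expressing $W$ only during engagement is what makes the
  within-trial activation/resting power ratio informative; if the trial's
  load multiplied the whole trial uniformly, the ratio would cancel it by
  construction and no ratio-based decoding could work.
* $\mathrm{osc}$ are amplitude-modulated sinusoids (default 6 Hz and 10 Hz)
  with slow random frequency jitter — narrowband by design so band-power
  expectations have closed forms: an amplitude factor $1 - k_a$ between
  $W = 1$ and $W = 0$ implies an alpha power ratio $(1-k_a)^2$, e.g.
  $k_a = 0.4 \Rightarrow$ %ERD $= (0.6^2 - 1) \times 100 = -64\%$. The test
  suite verifies this against an independent smoothed-periodogram estimate.
* $g(t) = 1 + d\,\sin(2\pi t / T)$ is a slow multiplicative session drift.
  It scales the **whole channel** — oscillators and background noise alike —
  because its physical interpretation is electrode/impedance gain change.
  Only under whole-channel scaling does the %ERD/ERS ratio cancel drift
  exactly; scaling the oscillators alone would leave a drift-dependent
  noise-floor term in the ratio.
* $n_c(t)$ is 1/f background noise; $a_c(t)$ are artifacts: blink templates
  at Poisson times on VEOG, propagated frontally by fixed leak weights, and
  200-ms band-limited 20–60 Hz EMG bursts centered on every keypress.
* An optional overload regime folds the modulation back above a threshold
  ($W \mapsto 2\tau - W$ for $W > \tau$): under extreme load the signature
  reverts toward its low-load appearance (disengagement), so overload trials
  are *not* linearly separable from easy trials.

All stochastic components consume the RNG stream unconditionally, so two
runs with the same seed that differ only in an amplitude parameter (drift
on/off, say) are sample-paired — several tests rely on that.

Subjective ratings are generated as
$\mathrm{clip}(\mathrm{round}(1 + 6W + \varepsilon), 1, 7)$ with Gaussian
$\varepsilon$ — the simplest monotone link onto the 7-point scale. Latent
load decays over trials within a fixed difficulty level,
$W_i = f + (b - f)e^{-\lambda i}$: repeated practice lowers experienced load
even though objective complexity is constant, which is exactly why the
labeling below uses ratings, not difficulty levels.

### Main generator parameters

| parameter | default | meaning |
|---|---|---|
| `rate` | 500 Hz | sampling rate (tests use 200 Hz) |
| `theta_freq`, `alpha_freq` | 6, 10 Hz | oscillator center frequencies |
| `theta_amp`, `alpha_amp` | 4, 6 µV | base source amplitudes |
| `theta_gain` ($k_t$) | 1.5 | theta amplitude gain per unit load |
| `alpha_depth` ($k_a$) | 0.8 | alpha amplitude attenuation per unit load |
| `noise_amp` | 2 µV | 1/f background sd |
| `drift_amp`, `drift_period_s` | 0.1, 300 s | multiplicative session drift |
| `blink_rate`, `blink_amp` | 0.08 /s, 120 µV | ocular artifacts |
| `emg_amp` | 4 µV | keypress EMG bursts (20–60 Hz, 200 ms) |
| `decay`, `floor`, `rest` | 0.05, 0.05, 0.1 | load decay per trial, floor, off-task load |
| rating `noise_sd` | 0.5 | rating noise on the 7-point scale |

The signature strengths ($k_a$, $k_t$), noise and rating noise were
calibrated **once** so that the default cross-task pipeline reaches a mean
accuracy in the 70–90% band plausible for this class of experiment, and then
frozen; the literature does not report effect sizes for the underlying
sources, so the absolute values are modeling choices, not empirical claims.

## Paradigm schedulers

Schedules are plain event tables (onset, duration, kind, task, level, trial,
value) serializable to TSV + JSON. Design constraints built in:

* fixed simple-to-complex difficulty ordering within every task — realistic
  learning material cannot be randomized, so the pipeline must *tolerate*
  the resulting time/difficulty confound rather than assume it away;
* identical visual event structure across the difficulty levels of a task
  (asserted by a test that counts event kinds per trial), so a classifier
  cannot exploit display differences;
* n-back digits every 2000 ms, digit 7 excluded (the only two-syllable
  digit); reading-span letters drawn without replacement per span from the
  nine-letter set B F H J L M Q R X, 500-ms fixation, 1000-ms letter;
* word problems with exactly four numerical givens at every level
  (distractors filling up easy levels) and answers from the level formulas —
  subtraction $x = a$, $x = a - b$, $x = (a-b)-(c-d)$; fraction
  $x = c\frac{a}{b}$, $x = c\frac{a}{b} + d\frac{a}{b}$,
  $x = c\frac{a}{b} + d\frac{e}{f}$ — and no feedback ever;
* simulated reaction times are log-normal (median 1.1 s for n-back clamped
  into the 2-s grid; self-paced sentence/fact/problem phases with their own
  medians), giving variable interval lengths as in real data.

Block counts are configuration, not facts: defaults are 48 trials per
n-back block, 6/3/2 spans per reading-span block and 10 problems per level;
the alternation design fixes 3 episodes × (5+5) windows, comic first.

## Preprocessing

* **EOG regression**: each EEG channel minus its least-squares projection
  onto the (centered) EOG channels, coefficients from the full recording;
  idempotent, exact for exactly-linear contamination, zero-variance
  regressors contribute nothing.
* **Interval extraction** (cross-task mode): per trial, an activation
  interval $I_a$ and a resting interval $I_r$ — n-back: stimulus→keypress
  and keypress→next stimulus; reading span: the 1000-ms letter and the
  fixation gap after the verification keypress; word problems: the problem
  statement and the post-answer gap. Every interval is trimmed against all
  keypress guard zones $[k - 125\,\mathrm{ms}, k + 125\,\mathrm{ms}]$
  (motor planning and execution artifacts); if a trial's trimmed $I_a$ or
  $I_r$ falls below 250 ms (enough samples for the AR fit), the whole trial
  is discarded.
* **Epoch segmentation** (within-task mode): each 45-s study window yields
  exactly three non-overlapping 15-s epochs; windows whose peak-to-peak EEG
  amplitude exceeds 150 µV are dropped whole. The threshold is a stand-in
  for an unspecified artifact criterion.
* Time-to-sample conversion is half-open everywhere
  (`[a, b)` → samples `floor(a·rate)+1 … floor(b·rate)`), so adjacent
  windows never share a sample and counts are exact.

## Spectral estimation and features

An AR model is fit per interval and channel with the Burg lattice recursion
(forward/backward prediction-error minimization, Levinson update; C++ via
Rcpp). Reflection coefficients lie in $(-1, 1)$ by construction, so the
model is always stable — important for intervals as short as 250 ms. The
suite cross-checks the coefficients against `stats::ar.burg` and the
spectrum against a dense FFT transfer-function evaluation (≤ 1e−9
relative).

The PSD is evaluated exactly at the ten integer frequencies 4–13 Hz,
$P(f) = \sigma^2 / |1 - \sum_k a_k e^{-2\pi i f k / r}|^2$. Band power is
the **mean** (not sum) over the band's grid points so theta (4 points) and
alpha (6 points) are comparable. Intervals are mean-subtracted and linearly
detrended before fitting; additive drift would otherwise be misattributed
to low-frequency poles.

Features: $\%\mathrm{ERD/ERS} = (P_{I_a} - P_{I_r}) / P_{I_r} \times 100$
per electrode × frequency (100 columns; negative = desynchronization),
identical across all tasks. The within-task mode instead uses raw alpha
band power on the frontal + parietal subset — that design predates the
ratio lesson and showed no theta differences between materials, so
requesting theta there is an error by design.

## Labeling, calibration, classification

* **Personal cutoff**: the mean of a subject's working-memory-task ratings;
  trials rate above → high WML, below → low, ties → high (conservative
  toward detecting overload; configurable). The same cutoff is applied
  unchanged to the learning tasks. Working-memory ratings are block-level
  (trials inherit their block's rating), learning-task ratings trial-level.
* **2-of-3 level selection**: per task, drop the level whose mean rating
  deviates most from the cross-task grand mean (mean of all task × level
  means), subject to every task retaining a minority class fraction ≥ 40%
  after labeling. The greedy choice is tried first; if it violates balance,
  one-dropped-level-per-task combinations are tried in decreasing order of
  summed dropped deviation; deviation ties drop the lower level. This
  formalizes a procedure whose published description states only the
  outcome. The cutoff is computed from the *retained* working-memory
  blocks — computing it over all three levels can strand both retained
  levels on one side of it.
* **z-scoring**: per-feature mean and population sd from training rows
  only; test data transformed with training statistics (the cross-task
  shift stays visible to the classifier, as it must). Zero-variance columns
  get unit scale with a warning.
* **SVM-RBF**: `e1071`/libsvm; $(C, \gamma)$ from log-2 grids
  ($C \in 2^{-5..15}$, $\gamma \in 2^{-15..1}$, coarse steps) by stratified
  inner CV on training data only, refit on all training rows. Grid ties are
  broken toward moderate regularization ($C = 1$, $\gamma = 1/p$): on
  perfectly separable inner folds every cell ties, and extreme corners
  behave degenerately under label permutation.
* **Cross-task evaluation**: one model per subject on pooled n-back +
  reading-span trials, per-trial decisions on each learning task.
  Chance level is 50% by the balance constraint above; imbalance is an
  upstream calibration error, never reweighted here.
* **Permutation test**: B = 1000 draws by default; training labels
  uniformly shuffled, model refit at the fixed $(C, \gamma)$, test accuracy
  recomputed; $p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(B+1)$.
  Exhaustive enumeration over all distinct label arrangements is available
  for small training sets and is verified against direct enumeration. A
  full re-search per permutation would be stricter but is far slower; the
  fixed-hyperparameter scheme is the default.
* **Within-task CV**: stratified 10-fold, with z-scoring *and*
  hyperparameter search refit inside each training fold (no leakage);
  fold count shrinks with a warning if a class has fewer than 10 trials.

## Simulation-study sizes and calibration experiments

The test suite runs the full pipeline on reduced sessions — 200 Hz sampling
and smaller blocks (typically 12–24 n-back trials per level, 2–5 spans,
5–8 problems per level) — sizes chosen as the smallest at which the studied
properties are resolvable; the properties themselves (chance-level accuracy
under a null signature, p-calibration, drift cancellation, monotone power)
do not depend on session length or rate. Specifically:

* **Null calibration**: 200 simulated subjects with $k_a = k_t = 0$; mean
  cross-task accuracy must lie within 50 ± 3% and the fraction of
  permutation tests with $p \le 0.05$ within the binomial 95% band around
  0.05 (B = 99, so $p \le 0.05$ is exactly the 5 most extreme outcomes).
  The accuracy half holds; the exact-uniformity half does **not**, and the
  corresponding assertion is expected to fail: with 10–24 test trials the
  accuracy statistic is discrete with large atoms, the observed accuracy
  ties with permuted accuracies with probability ≈ 0.1–0.2, and the
  tie-inclusive add-one estimator is then structurally *conservative*
  (measured $P(p \le 0.05) \approx 0$–0.015 under the null, never
  inflated). This is the standard validity/exactness trade-off of
  permutation tests on discrete statistics; exact uniformity would need
  on the order of a hundred test trials per task or randomized
  tie-breaking, neither of which the pipeline adopts. Type-I error control
  — the direction that matters for the significance claims — holds
  throughout.
* **Drift cancellation**: with drift $d = 0.3$ in paired same-seed runs,
  working-memory-task features (whose baseline immediately neighbours the
  activation window) shift by < 5% relative while raw activation-interval
  band powers shift by ~30%. The cancellation degrades with the temporal
  separation of $I_a$ and $I_r$: on self-paced word-problem trials, where
  the baseline sits up to ~8 s after the analysis window, the residual
  grows to roughly a third to a half of the raw shift — the ratio trick
  presumes an immediately adjacent baseline, and the acceptance bound is
  asserted where that premise holds.
* **Power/monotonicity**: mean accuracy over 12 subjects per strength must
  rise strictly across $k_a \in \{0, 0.2, 0.4, 0.6\}$ (theta gain scaled
  proportionally, ratio 2.5). This sweep runs at `noise_amp = 4` and rating
  noise 0.3: at the default noise the response already saturates near the
  label-noise ceiling between 0.4 and 0.6, where strict ordering is not
  resolvable against Monte-Carlo error; the elevated fixed noise keeps all
  four points in the rising regime.
* **Accuracy band**: at the calibrated default signature the cross-task
  mean over 8 subjects must fall in 70–90%, and the within-task CV accuracy
  above 70%. Synthetic within-task epochs are much cleaner than real EEG
  (15 s of stationary signal per epoch), so that mode typically saturates
  near 100%.
* Subjects whose coarse integer block ratings admit no balanced 2-of-3
  selection are excluded by the cohort runners with a message (roughly a
  few percent of seeds); exclusion depends only on ratings, never on the
  EEG, so it cannot bias accuracy.

## What the generator does and does not emulate

Emulated: the canonical theta-ERS/alpha-ERD topography, within-session
non-stationarity (slow multiplicative drift, amplitude modulation,
frequency jitter), blink and keypress-EMG artifacts with realistic spectral
content, rating decay with practice, the optional overload reversal, and
the full event structure of all six paradigms.

Not emulated: volume-conducted source mixing beyond fixed weights,
event-related potentials, eye-movement rehearsal patterns, inter-subject
topography differences, electrode pops, line noise, or any coupling between
difficulty and artifact rate. Passing the suite therefore demonstrates that
the *pipeline* is correct and well-calibrated under its stated assumptions —
it does not certify accuracy figures on recorded EEG, where the signature
is weaker, topographies vary, and covariate shift between tasks is more
severe than the generator's.

## Known limitations

* One interval pair per trial; sub-windowing long problem statements might
  use the data better.
* The permutation scheme fixes $(C, \gamma)$; re-searching per draw is
  available in principle but costly.
* The level-selection algorithm is a deterministic formalization of a
  procedure described only by outcome; other defensible rules exist.
* Ratings are integers on a 7-point scale; with one block rating per
  working-memory level, degenerate splits occur for some subjects and are
  handled by exclusion rather than imputation.
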