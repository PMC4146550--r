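---
title: "A hybrid two-branch motor-imagery BCI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid two-branch motor-imagery BCI: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridbci)
```

# The problem

Two-class motor-imagery brain-computer interfaces decode imagined (or
attempted) movements from scalp EEG and turn each decoded trial into one of
two commands. Severely paralyzed users produce weak, unstable and sometimes
atypical sensorimotor signals, so a practical system needs (i) more than one
neural signature to fall back on, (ii) classifiers that remain calibrated as
the signals drift, and (iii) a way to withhold commands when the evidence is
too weak to act on. This package implements that full loop — signal model,
classifiers, adaptation, threshold gating, a two-action game application and
the evaluation stack — together with a ground-truth EEG generator, so that
every stage is testable without any patient data.

# Signal model and the two feature branches

EEG arrives as a channels-by-samples matrix in microvolts at sampling rate
`fs`, with a marker table of cue events (`recording()`). The front end
low-pass filters at 45 Hz and resamples to 100 Hz
(`lowpass_downsample()`); trials are cut with half-open windows in
milliseconds relative to each cue (`epoch()`).

**Oscillatory branch (ERD/rebound).** Motor imagery desynchronizes the
sensorimotor rhythms: band-limited power over the contralateral motor
cortex drops during the trial (ERD) and beta-band power transiently
overshoots after trial end (rebound). The branch band-pass filters in a
configurable band (default 8–12 Hz, order-5 Butterworth), estimates per
trial the spatial covariance over a discriminative interval, and fits
Common Spatial Patterns (`fit_csp()`): the generalized eigendecomposition
of $(C_1, C_1 + C_2)$, where $C_c$ is the trace-normalized, class-averaged
covariance. Each component's eigenvalue is the fraction of normalized
variance it carries for class 1, so the two ends of the spectrum are the
discriminative filters and the per-component eigenvalues of the two classes
sum to one. Features are the log-variances of the selected components
(`csp_logvar()`), and the visualizable scalp patterns are the inverse of
the filter matrix.

**Slow-potential branch (LRP).** Movement preparation also produces a slow
lateralized potential. The branch filters 0.2–4 Hz (order-5 Butterworth),
subtracts the per-channel mean of the 300 ms before cue onset
(`baseline_correct()`), and takes each channel's mean amplitude over a
class-discriminative interval as the feature vector (`lrp_features()`).

Channel- or feature-wise discriminability is quantified by the signed,
scaled area under the ROC curve, `ssauc_map()`: $2(\mathrm{AUC} - 0.5)
\in [-1, 1]$, computed by rank sums with ties counting one half.

# Classification, adaptation and the meta-combination

Each branch feeds a shrinkage-regularized linear discriminant
(`train_shrinkage_lda()`): the pooled covariance is shrunk toward a scaled
identity, $(1-\gamma)\Sigma + \gamma\nu I$ with $\nu = \mathrm{tr}(\Sigma)/d$,
and $\gamma$ chosen by the analytic Ledoit–Wolf-style estimator — essential
when the number of features approaches the number of calibration trials.
The discriminant is $w = \Sigma_\gamma^{-1}(\mu_2 - \mu_1)$,
$b = -w^\top(\mu_1 + \mu_2)/2$; negative scores vote for class 1, positive
for class 2.

During labeled (CopyTask) operation both LDAs are re-estimated after every
trial (`adapt()`): the true class's mean and the pooled covariance are
updated as exponential moving averages with rate $\eta = 0.03$, and $w, b$
are recomputed from the updated moments, which corrects bias drift
implicitly. The shrinkage coefficient is frozen after initial training: the
analytic estimator is a function of a full sample, not of a single trial,
and re-estimating it from EMA moments would conflate shrinkage with drift.
In FreeMode no labels exist and adaptation is a contract violation, which
`adapt()` enforces.

The two branch outputs are combined as an individually weighted sum
(`combine()`). Raw LDA scores live on arbitrary, branch-specific scales, so
each member's output is first divided by the standard deviation of its
training-set scores; without this the weights would be meaningless across
feature scales. Default weights are proportional to
$\max(0,\ \mathrm{CV accuracy} - 0.5)$ per branch, so an uninformative
branch is switched off; the experimenter can also pin the active output to
a single branch. Decisions are gated by a threshold $\theta$
(`decide()`): action A below $-\theta$, action B above $+\theta$, and
**noDecision** on the closed interval between — no command is emitted, but
session time is still spent. `calibrate_theta()` picks the smallest
$\theta$ reaching a target precision (default 0.8) on labeled outcomes,
since no canonical threshold values exist to copy.

# The closed loop

`hybrid_bci()` fits everything from one cued recording and returns a
classed model with `print`, `summary`, `coef`, `predict` and `plot`
methods. `run_copy_task()` replays a cued stream against the model with
strictly causal filtering, scores a sliding 1 s window every 100 ms,
accumulates the frame scores by their mean, judges each trial by the sign
of the accumulated output (the threshold plays no role in CopyTask
correctness), and adapts both branch LDAs after every trial.
`run_free_mode()` does the same scoring on question-mark cues, gates by
$\theta$, never adapts, and applies every decided action to the Connect-4
game, where a rejected drop into a full column is a logged no-op so control
errors stay visible.

Within a trial the oscillatory frame score is windowed by construction; the
slow-branch feature is defined over a fixed interval, so its frame score
uses that interval clipped to the time elapsed so far (at least 200 ms),
and earlier frames fall back to the oscillatory branch alone. This keeps
every frame strictly causal while matching the features the classifier was
trained on.

# Evaluation stack

* `binary_accuracy()` — fraction of correct trials; chance is 50% for two
  balanced classes. CopyTask scores every labeled trial (sign-based);
  FreeMode scores decided trials only. Consecutive trials are also grouped
  into blocks of at least 20.
* `chance_test()` — one-sided exact binomial tail
  $P(X \ge k \mid n, 1/2)$, with Pearson's $\chi^2$ (1 df) reported as a
  cross-check. The binomial is exact at session-sized counts; the
  significance flag uses 0.05.
* `wolpaw_bits()` / `itr_with_pauses()` — bits per selection
  $\log_2 N + P\log_2 P + (1-P)\log_2\frac{1-P}{N-1}$, and bits per minute
  with **all** elapsed time in the denominator, noDecision trials and
  pauses included; accuracy is computed over decided trials. The
  time-inclusive, decided-accuracy convention is documented rather than
  assumed, and both bases can be recomputed from the session log.
* `crossval_accuracy()` — stratified 5-fold cross-validation where CSP and
  LDA are fitted strictly inside each training fold; fitting spatial
  filters outside the folds leaks label information, which the test suite
  checks by demanding chance-level results on label-shuffled data.
* `spectral_screening()` — Welch spectra per channel under eyes-open /
  eyes-closed conditions plus 8–12 Hz band power per channel, the standard
  pre-study check for usable idle rhythms.

# The synthetic generator

`generate_recording()` emulates exactly the signal classes the pipeline
targets, with known ground truth:

* per-channel 1/f (pink) background noise at unit variance;
* two band-limited sources mixed through smooth Gaussian scalp bumps
  centered near C3 and C4 of a 16-channel motor montage (no forward head
  model — the tests need topographies, not physics);
* ERD: the class-specific source's variance is multiplied by
  $1 - \texttt{erd\_depth}$ during that class's trials;
* rebound: variance multiplied by `rebound_gain` for 1 s starting 500 ms
  after trial end;
* LRP: a transient half-sine deflection of `lrp_amplitude` microvolts and
  ~1.5 s duration starting 2 s after cue onset, on the contralateral motor
  channel. A full-trial DC ramp was rejected deliberately: its energy lies
  below the 0.2 Hz high-pass edge of the slow branch, so it would vanish in
  filtering by construction, whereas real readiness potentials are
  transient;
* drift: a per-trial rotation of the mixing columns in their own plane
  (`drift_rate` degrees/trial), modeling session-to-session
  nonstationarity;
* `scripted_user()` wraps the generator for FreeMode tests: per-trial
  classes follow a scripted intent sequence at a configurable
  `controllability` (the probability the intended signature is actually
  expressed).

Defaults are 16 channels, 100 Hz, 5 s trials, 3 s pauses, 8–12 Hz ERD at
depth 0.5, rebound gain 2, 5 µV LRP, SNR 1 — a mid-range subject a
practitioner would call realistic, chosen once and not revisited. What the
generator does **not** model: eye and muscle artifacts, volume conduction,
electrode impedance changes, and the atypical spectra (absent idle rhythms)
some severely injured patients show. Passing tests on this generator
therefore demonstrate correctness of the machinery and recoverability of
planted effects, not clinical performance.

# Numerical choices

* Filters are designed in zero-pole-gain form and paired into second-order
  sections; an order-5 band-pass with a 0.2 Hz edge is numerically unusable
  as one expanded polynomial but unconditionally stable as biquads. Causal
  filtering is mandatory on the online path; zero-phase (forward-backward,
  odd-reflection padding) is available offline. The design was verified
  against an independent implementation at corner and center frequencies to
  ~1e-12.
* Rank-deficient CSP covariances get `1e-8 * trace * I` added, with a
  warning — the realistic regime for 16 channels and few trials.
* Pattern signs are normalized so the largest-magnitude coefficient is
  positive; scalp-map sign is arbitrary.
* Zero-variance components are floored at machine epsilon before the log.
* Marker resampling rounds down; at 100 Hz and multi-second trials,
  sub-sample cue latency is irrelevant.
* Seeds: every stochastic routine takes an explicit seed; the generator
  refuses to run without one.

# Design decisions that were genuinely open

* **Accumulation** is the arithmetic mean of frame scores; sum and decaying
  integrals are behaviorally equivalent up to the threshold scale, and the
  mean makes $\theta$ interpretable on the score scale.
* **CopyTask correctness** is sign-based (no threshold); $\theta$ gates
  only FreeMode actions, where an unintended command has a cost.
* **The win/block/random game opponent.** The original computer heuristic
  is not specified anywhere; this package reconstructs it as: play an
  immediately winning column, else block an opponent's immediate win
  (lowest column index first — a double threat can only be blocked once,
  which is the only way a random player ever wins), else a uniformly random
  legal column. Measured over 10,000 seeded games against a uniformly
  random player this reconstruction wins ~96% with ~0.3% draws — far
  stronger than the originally reported 70%/20%/10% split, so that split
  should be read as a property of the unpublished original heuristic, not
  as a reproducible constant of the game. The simulation is retained as a
  calibration experiment (`simulate_matches()`), and the acceptance suite
  reports the measured split honestly.
* **Threshold sweep monotonicity.** Raising $\theta$ provably never turns
  a noDecision into a decision, so the decided-trial count is
  non-increasing — asserted strictly. Decided-trial *precision*, however,
  cannot be exactly monotone on any finite session that contains an error:
  dropping a correct low-score trial moves precision from $n/m$ to
  $(n-1)/(m-1)$, a strict decrease bounded by $1/m$. The tests therefore
  assert monotonicity up to that single-trial discreteness bound, which is
  the systematic property the sweep is meant to have.
* **FreeMode entry** ("sufficient control") is exposed as a configurable
  CopyTask accuracy threshold (default 0.7) and enforced by the caller,
  not hard-coded.
* **Continuous vs per-epoch filtering**: the online engine filters the
  continuous stream once (causally) and epochs afterwards, which is both
  faster and closer to a real-time implementation; per-epoch filtering
  remains possible through `bandpass()` on an epoch set.

# Problem sizes used by the test and acceptance suites

The suites run end-to-end on deliberately modest sizes chosen as the
package's own desk-scale conditions: 20–50 trials per class per synthetic
session, 16 channels at 100 Hz, 5-fold cross-validation, 20 label
reshuffles for the leakage suite, 20 seeds for the adaptation-benefit
property, and 10,000 games for the Connect-4 baseline. At these sizes the
full suite completes in a few minutes while every statistical assertion
retains a comfortable margin over its sampling noise.

# Known limitations

* One-dimensional montage geometry: scalp topographies are profiles over a
  channel axis, not interpolated 2-D scalp maps.
* The generator's drift is a smooth rotation; abrupt electrode shifts or
  amplifier rail events are not modeled.
* `adapt()` implements supervised adaptation only — unsupervised and
  probabilistic variants are out of scope.
* Vendor EEG file formats are not read; the recording bundle
  (`header.json` + float32 `signal.bin` + `markers.csv`) and a CSV fixture
  dialect are the only on-disk formats.
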