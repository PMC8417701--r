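---
title: "Time-aware validation of mental workload classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-aware validation of mental workload classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mwbench)
```

## The estimation problem

`mwbench` studies binary mental-workload estimation (LOW vs. HIGH task
demand) from multimodal physiology recorded over a structured session:
four 8-minute task blocks whose condition alternates H-L-H-L or
L-H-L-H, interleaved with five 1-minute rest blocks. Every analysis
operates on non-overlapping 6-second epochs.

Three sensor families contribute features:

* **EEG** — absolute spectral power in θ (4–8 Hz), α (8–12 Hz),
  β (12–30 Hz) and γ (30–45 Hz) from a multitaper estimate, and the
  engagement index `EI = β / (α + θ)`, at 20 retained scalp sites. The
  classified EEG vector is {β, γ, EI} × 20 electrodes = 60 features:
  these are the quantities that rise reliably with workload, while θ/α
  changes are weaker and less consistent.
* **ECG** — heart rate (`60000 / mean(RR ms)`) and SDNN (sample SD of
  the RR intervals) per epoch, after Malik-rule artifact cleaning, each
  normalized by subtracting its mean over the immediately preceding
  rest block. Higher workload raises HR and lowers SDNN.
* **Eye tracking** — blinks inferred from missing-sample runs
  (70–500 ms), fixations from a dispersion-threshold (I-DT) detector,
  per-AOI fixation counts and dwell durations over the five analyzed
  screen regions, and mean pupil dilation (z-scored per participant
  across the session). Higher workload produces more and shorter
  fixations, a dwell shift toward the flight display (AOI 2) and the
  path-monitoring sub-area (AOI 4.1), and larger pupils; blink latency
  carries no injected effect and is excluded from the classified set
  (13 ET features).

Behavioral performance is scored per sub-task: pop-up detection
correctness and response time, working-memory (ATC channel recall)
correctness, and a flying score per ATC segment,

```
y = sum_n dnorm(d(x_n, mu), 0, sigma) - 0.5 * (# 50-ms ticks in a restricted zone)
```

with σ = 20 degrees, headings sampled every 500 ms, and `d` the minimal
angular difference wrapped to (−180°, 180°]. Without wrapping the score
would misbehave for commanded headings near north (359° vs. 1° would
count as a 358° error); with it the score is invariant to adding 360°
to any heading and strictly decreases as any deviation grows.

## The four validation designs

The package's central contribution is the comparison of two validation
philosophies at two scopes:

* **Traditional intra-subject.** All of a participant's epochs are
  pooled; a seeded, stratified 70% subsample tunes hyperparameters via
  5-fold grid search; the tuned configuration is evaluated by
  stratified 10-fold cross-validation over *all* epochs. The tuning
  rows deliberately reappear in the evaluation — this mirrors the
  published procedure and is part of why the traditional estimate is
  optimistic; `clean = TRUE` provides a stricter variant.
* **Ecological intra-subject.** The first LOW and first HIGH blocks
  train, the remaining two test. Within each phase × condition the
  time-ordered epochs are cut into three contiguous subsets S1–S3 of
  near-equal size (remainders go to the earliest subsets), combined
  into overlapping groups G1 = S1+S2, G2 = S2+S3, G3 = S3+S1; every
  epoch belongs to exactly two groups. Each of the 9 training
  combinations (one LOW group × one HIGH group) is tuned by 5-fold grid
  search inside itself, fitted, and evaluated on each of the 9 test
  combinations: 81 scores per classifier per participant. All 9 × 9
  combinations are enumerated exhaustively in a fixed train-major
  order, so runs replay deterministically.
* **Traditional inter-subject.** Leave-2-out over all unordered
  participant pairs; grid search on the training pool; each held-out
  participant tested separately.
* **Ecological inter-subject (partial transfer).** The held-out pair's
  *first* LOW and HIGH blocks join the training pool; only their *last*
  blocks are tested. Within every held-out participant, training rows
  strictly precede test rows.

Every ecological evaluation carries a time-separation audit
(`max(training epoch time) < min(testing epoch time)` per condition and
participant) that is asserted on every fold.

Accuracies are compared against the **adjusted chance level**: the
smallest `k*/n` such that a Binomial(n, ½) variable reaches `k*` with
probability ≤ α. With few test trials, accuracies well above 50% still
arise by guessing; the adjustment shrinks toward 0.5 as `n` grows.

Seven classifier families are benchmarked behind a uniform fit/predict
surface: KNN, decision trees and RBF SVM from their standard
implementations, Gaussian naive Bayes and LDA likewise; AdaBoost.M1
over depth-1 stumps and a shrinkage-regularized quadratic discriminant
(`Σ_c ← (1−λ)Σ_c + λ·mean(diag(Σ_c))·I`) are implemented in-package.
The regularization is what lets a quadratic rule operate when a
training group holds fewer rows (≈54 in the ecological design) than
the 60-dimensional EEG set; λ is tuned by the grid search. Features
are z-scored using training rows only, per fold, so scale-sensitive
classifiers work without leaking test statistics into the fit.
Hyperparameter grids are small, fixed and documented
(`default_grids()`): neighbor counts {3, 5, 9}, tree depths {2, 4, 8},
boosting rounds {20, 50}, QDA shrinkage {0.2, 0.5}, SVM cost
{0.1, 1, 10}.

## The synthetic session generator

No public recording of this protocol exists, so the package ships a
generator whose defaults encode the study conditions, and every
downstream stage is tested against it.

* **EEG** (256 Hz, 20 sites + 2 EOG): 1/f background (relative
  amplitude 0.25) plus band-limited Gaussian oscillations per band.
  Under HIGH load, β/γ power is multiplied by `eeg_beta_gamma_gain`
  (default 1.5) at the 10 effect sites (Fp2, FC5, FC6, T7, T8, CP5,
  P8, O1, Oz, O2) and parieto-occipital α is slightly reduced (gain
  0.9). Each band's amplitude is modulated by a mean-one lognormal
  slow process (log-SD 0.6, ~5 s time constant) — the bursting that
  makes real band power vary between epochs. A blink source (smooth
  300-ms bumps, ~12/min) mixes into frontal channels with a known
  topography and appears on the VEOG channel, giving the ocular-removal
  stages a ground truth. Oscillation synthesis keeps each band's
  support 0.5–1 Hz inside its nominal edges so that neither the
  spectral ramps nor multitaper smoothing (~0.7 Hz at 6-s epochs)
  pushes one band's power into a neighbor's analysis range.
* **ECG** (256 Hz): a template-QRS train whose RR intervals are drawn
  sequentially with mean set by the instantaneous heart rate (resting
  baseline, +`hr_delta` = 5 bpm under HIGH, plus a slow baseline wander
  of SD 4.5 bpm and ~20 s time constant) and SD set by the condition
  (`sdnn_base` = 50 ms at rest/LOW, −`sdnn_delta` = 10 ms under HIGH).
  The wander is nearly constant within a 6-s epoch, so the configured
  SDNN is the epoch-scale RR variability while epoch-mean HR still
  fluctuates realistically between epochs.
* **Eye tracking** (100 Hz): a fixation/saccade point process with
  lognormal fixation durations (broadly dispersed, log-SD 0.6; mean
  shortened by `fixation_duration_gain` = 0.85 under HIGH and cycles
  accelerated by `fixation_rate_gain` = 1.2), AOI choice from a
  categorical dwell distribution that shifts probability
  (`aoi_dwell_shift` = 0.1) onto AOI 2 and AOI 4.1 under HIGH, blink
  gaps as the *only* missing samples (enforced ≥ 1 s apart so the blink
  count is exactly recoverable), and a pupil channel (baseline ~3 a.u.,
  +0.12 under HIGH, slow fluctuation SD 0.12 with ~4 s time constant).
* **Behavior/events**: 15 pop-up probes (21–24 s spacing) and 6 ATC
  commands (80–82 s spacing) per task block with condition-dependent
  correctness and response times, a 2-Hz heading trace relaxing toward
  the commanded heading with condition-dependent deviation, a 20-Hz
  restricted-zone occupancy stream, and an ISA rating at each rest
  onset.
* **Non-stationarity**: `drift_magnitude` applies a zero-mean linear
  multiplicative ramp across the session to band amplitudes, the RR
  baseline, and the pupil baseline (default 0.2, i.e. ±10% across the
  session). Time-on-task drift is the effect under study; a linear ramp
  is the simplest form with the right character, and it is the *only*
  block-scale non-stationarity — the stationary noise processes above
  have time constants at or below the epoch scale precisely so that
  the drift knob alone controls the traditional-vs-ecological contrast.

Effect magnitudes for EEG are not published; defaults were calibrated
once so that single-modality benchmark accuracies land in a plausible,
non-saturated 55–75% band (traditional intra: ECG ≈ 0.74, EEG ≈ 0.73,
ET ≈ 0.71 at these defaults), matching the regime of the reference
results rather than any specific number.

What the generator does **not** emulate: volume conduction and realistic
EEG topography beyond per-site gains, ECG morphology beyond detectable
R waves, saccade dynamics, measurement-device clock drift, artifacts
other than ocular ones, and between-participant effect-size
heterogeneity (baselines vary; effect magnitudes do not). Passing tests
therefore demonstrate that the pipeline recovers the statistical
structure it claims to measure — not that it would reach the same
accuracies on real recordings.

## Numerical choices

* **Epoching.** The 6-s grid is anchored at each block start; a
  trailing remainder shorter than the epoch length is discarded rather
  than padded. Epoch boundaries are taken on the highest-rate stream;
  each slower stream is cut at its own sample nearest the reference
  boundary (alignment error ≤ half its sample period). Boundary indices
  are shared between consecutive epochs (half-open intervals), so no
  sample lands in two epochs.
* **Filtering.** The band-pass (default 1–45 Hz) is applied in the
  frequency domain as the squared magnitude of an order-2 Butterworth
  high-pass cascaded with an order-6 low-pass — the response a
  forward-backward IIR pass would have, exactly zero-phase and stable
  at a 1-Hz corner. A 60 Hz tone is attenuated by > 20 dB. The γ band
  (30–45 Hz) motivates the 45-Hz corner; `high = 40` gives the stricter
  variant in which γ is effectively 30–40 Hz.
* **Ocular removal.** Default is symmetric FastICA (logcosh contrast,
  whitening by eigendecomposition, max 100 iterations, tolerance 1e-3);
  components correlating with any EOG channel above |r| = 0.8 are
  zeroed. If the decomposition fails to converge the code falls back to
  least-squares regression on the EOG channels with a warning;
  `method = "regression"` selects that path directly and is the
  pragmatic choice for large batch runs (about 3× faster per session).
  Average re-referencing follows removal.
* **Multitaper.** DPSS tapers via the tridiagonal eigenproblem,
  time-bandwidth 4, 7 tapers, cached per epoch length. Band power is
  the one-sided density integrated over half-open bands, so adjacent
  bands never share a frequency bin.
* **R-peak detection.** High-pass at 1 Hz, squared-derivative energy
  smoothed over 60 ms, two-stage adaptive threshold: provisional peaks
  above half the maximum amplitude set the typical R amplitude, and
  candidates above 0.5× its median are accepted (with a 250-ms
  refractory period, then refined to the local maximum of the filtered
  trace). The two-stage rule matters: noise maxima between beats would
  otherwise dominate the median and drag the threshold down.
* **Malik rule.** An interval is removed when it deviates from the
  previous *retained* interval by more than 20% of it; the first
  interval is always kept. Comparison against the retained predecessor
  (rather than the raw one) makes the rule idempotent and keeps a
  normal interval after an artifact.
* **SDNN** uses the sample (n−1) standard deviation. On 6-s epochs it
  rests on 4–10 intervals and is accordingly noisy; no small-sample
  correction is applied.
* **Feature selection** tests per-participant condition *means* (not
  pooled epochs), respecting the repeated-measures structure: paired
  t-test when the differences pass Shapiro-Wilk at 0.05, Wilcoxon
  signed-rank otherwise; no multiple-testing correction, α = 0.05.
  Constant features are dropped with a warning.
* **Degenerate inputs.** Zero α+θ power gives a missing engagement
  index (not infinity); flat-line ECG gives an empty, flagged RR
  series; an all-missing gaze epoch gives no fixations; an empty
  heading trace scores 0 with a warning; epochs shorter than the filter
  warm-up are rejected with advice to use longer epochs.
* **Determinism.** Every stochastic step (generation, subsampling, fold
  assignment, grid-search folds) derives from an explicit seed through
  a deterministic label-hash; `run_benchmark()` reproduces every
  accuracy bit-for-bit under the same master seed, and seeded code
  restores the caller's RNG state.

## Validating the generator: parameter recovery

`recover_effects()` closes the loop between generator and extractors.
Each estimator is chosen to be unbiased for the quantity it recovers:

* HR: mean rest-normalized heart rate difference over epochs (cohort
  orders alternate H-L-H-L / L-H-L-H, so the linear drift cancels in
  the cohort mean).
* SDNN: per-epoch sample SD without Malik cleaning — on artifact-free
  beats the 20% rule truncates the RR tails and would shrink the SD by
  ~1%, a bias visible at Monte-Carlo precision.
* Pupil: the condition coefficient of a per-participant linear model on
  condition plus a linear time term, so the drift is estimated jointly
  instead of inflating the contrast's variance.
* β/γ gain: the HIGH/LOW ratio of oscillatory band power at the effect
  sites, geometric-averaged across order-balanced participants (drift
  biases are exactly reciprocal between the two orders). Epochs are
  filtered and regression-cleaned but *not* re-referenced — the
  channel-mean subtraction mixes sites and dilutes a site-level power
  contrast — and the aperiodic background, fitted per channel as
  `a/f + w` over 50–90 Hz where the generator places no oscillation, is
  subtracted before the ratio. Without that correction the 1/f floor
  and broadband cleaning residue bias the recovered gain low by a few
  percent, which Monte-Carlo precision resolves easily.

The test suite runs this recovery on 20 seeded cohorts (6 participants
with 2-minute blocks for the cardiac/ocular arm; 2 order-balanced
participants for the spectral arm, where EEG synthesis dominates cost)
and requires each recovered value to sit within 3 Monte-Carlo standard
errors of its configured value.

## Design comparisons on synthetic data

With drift present, traditional intra-subject accuracy exceeds the
ecological estimate — the optimism the ecological design exists to
expose. The suite verifies this as a paired sign test across 12 seeded
sessions (6-minute blocks) at `drift_magnitude = 0.4`, and verifies the
converse at drift 0 as a TOST equivalence within a 5-percentage-point
margin. Both arms use a single-feature probe (pupil dilation with
Gaussian naive Bayes): with multi-feature sets the two designs differ
by a few points even without drift, purely because ecological training
groups hold ~2/3 of one block and sample-size effects depress any
classifier's accuracy — a learning-curve artifact, not
non-stationarity, and the probe removes it. An explicit equivalence
margin is used for the no-drift arm because asserting a
*non-significant* difference with an underpowered test would be
vacuous.

A permuted-label calibration closes the loop on the chance-level
machinery: with labels shuffled, the fraction of benchmark cells whose
mean accuracy exceeds the adjusted chance level at α = 0.05 is
compatible with 5%.

## Problem sizes

The packaged tests and the acceptance script favor reduced
configurations chosen for desk-scale runtimes while keeping every
estimator in its intended regime: 2-minute task blocks for recovery
cohorts (20 epochs per block), 4–6-minute blocks for design
comparisons, cohorts of 4–6 participants for the inter-subject designs
(C(n,2) folds), and the LDA/GNB/SVM subset of classifiers for factorial
runs. Full-protocol sessions (8-minute blocks, 320 task epochs, all
seven classifiers) run through exactly the same code paths and are
exercised where cheap.

## Known limitations

* The SDNN estimator on 6-s windows is noisy and slightly biased low;
  results should be read as a short-window HRV proxy, not a clinical
  SDNN.
* Ecological intra-subject groups are small by construction, so
  classifier learning-curve effects are entangled with
  non-stationarity effects in any multi-feature comparison between the
  designs (the single-feature probe above is the package's way of
  separating them).
* The traditional intra design reuses tuning rows in its final 10-fold
  evaluation by construction; use `clean = TRUE` for a leakage-free
  variant.
* The generator's effects are homogeneous across participants up to
  baseline shifts; between-participant transfer (inter designs) is
  therefore easier here than on real cohorts, where effect
  heterogeneity dominates.
* AdaBoost uses axis-aligned depth-1 stumps; feature interactions are
  only captured through boosting depth in rounds, not within a learner.
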