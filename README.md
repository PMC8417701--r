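# mwbench

Mental workload estimation from multimodal physiology, with validation
designs that respect time.

## The problem

Passive brain-computer interfaces estimate an operator's mental state —
here a binary LOW/HIGH workload level — from physiological recordings:
EEG spectral band powers and the engagement index `EI = β / (α + θ)`,
cardiac features (heart rate `HR = 60000 / mean(RR)` and the SDNN
heart-rate variability, the standard deviation of normal-to-normal RR
intervals), and eye-tracking features (fixation count and duration,
per-AOI dwell, blink statistics, pupil dilation). Classification
pipelines over such features are usually validated by pooling all of a
session's epochs and splitting them at random. Because physiological
signals drift with time on task (non-stationarity), that *traditional*
validation is optimistic: at deployment a classifier is always trained
on earlier data and applied to later data. The *ecological* designs
implemented here enforce exactly that ordering — training epochs
strictly precede testing epochs — and quantify how much accuracy the
traditional estimate overstates.

`mwbench` implements, for a protocol of four 8-min task blocks
(alternating LOW/HIGH, interleaved with five 1-min rests, 6-s epochs):

* a session data model with cross-stream nearest-timestamp epoching;
* a synthetic multimodal session generator (EEG + EOG, ECG,
  eye-tracking, heading/zone behavior and task events) with configurable
  workload effects and a tunable slow drift producing time-related
  non-stationarity;
* the three feature extractors and behavioral task scores, including the
  Gaussian heading-compliance score
  `y = Σ_n (1/(σ√(2π))) exp(−d(x_n, μ)²/(2σ²)) − 0.5 · zone_ticks`
  with σ = 20°, a 0.5 penalty per 50 ms spent inside a restricted zone,
  and wrapped angular differences;
* significance-based feature selection (paired t / signed-rank tests on
  per-participant condition means) and the seven sensor-combination
  feature sets (EEG: 60 columns, ECG: 2, ET: 13);
* four validation designs over seven classifier families (KNN, decision
  tree, AdaBoost, Gaussian naive Bayes, LDA, regularized QDA, RBF SVM):
  traditional intra (70% grid-search tuning + stratified 10-fold CV),
  ecological intra (time-ordered thirds S1–S3 per phase and condition,
  overlapping groups G1 = S1+S2, G2 = S2+S3, G3 = S3+S1, 9 training × 9
  testing combinations = 81 scores), traditional inter
  (leave-2-participants-out) and ecological inter (partial transfer:
  the held-out pair's first blocks join the training pool, only their
  last blocks are tested);
* the adjusted chance level `k*/n`, the smallest accuracy that beats
  random guessing at level α under an exact Binomial(n, ½) test.

## Worked example

Generate one participant's session (4-min blocks to keep this quick),
extract the per-epoch feature table, and compare the two intra-subject
validation designs on the cardiac features:

```r
library(mwbench)

cfg <- effect_config(task_block_s = 240, seed = 42)
s   <- generate_session("P01", cfg, order = "HLHL",
                        streams = c("ecg", "et"))
tbl <- extract_features(s, sensors = c("ecg", "et"))

aggregate(cbind(ecg_hr, et_nfix, et_fixdur) ~ condition, tbl, mean)
#>   condition ecg_hr et_nfix et_fixdur
#> 1      HIGH  7.142   15.35     0.370
#> 2       LOW -0.349   13.65     0.416

sets <- feature_sets()
mean(traditional_intra_cv(tbl, sets$ECG, "LDA", seed = 42))  # 0.788
mean(ecological_intra_cv(tbl, sets$ECG, "LDA", seed = 42))   # 0.711

adjusted_chance_level(nrow(tbl))
#> adjusted chance level: 0.5625 (n = 160, alpha = 0.05)
```

Rest-normalized heart rate sits ~7 bpm higher under HIGH load, the
participant fixates more and for shorter durations, and the
time-separated (ecological) estimate is lower than the traditional one
— both comfortably above the chance level adjusted for 160 trials.
`run_benchmark()` expands this to the full factorial of designs ×
scopes × feature sets × classifiers and returns the per-cell accuracy
distributions; `generate_cohort()` + `assemble_cohort()` produce
multi-participant tables for the inter-subject designs;
`select_features()` applies the load-significance retention rule.

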