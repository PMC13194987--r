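---
title: "Predicting smoking lapses and cravings from passive smartphone sensing: models and methods"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Smokers attempting to quit lapse at moments that are hard to anticipate
from self-report alone. If the micro-movements a smartphone passively
records (accelerometer, gyroscope, magnetometer) carry a signature of the
minutes leading up to a smoking-related event, a cessation app could
deliver support inside the window where it matters. `smokesense`
implements that analysis as a reproducible pipeline: sensor streams and
event logs in, windowed and balanced datasets, four deep sequence
classifiers, and three evaluation designs out.

Cohorts of this kind — weeks of continuous multi-sensor recording paired
with real-time event logging across a quit attempt — are not openly
released, so the package treats the *synthetic cohort generator* as a
first-class, tested component. Everything downstream is exercised against
data whose ground truth is known by construction.

# The synthetic cohort

## Study design encoded in the defaults

`cohort_config()` defaults describe the emulated design: 17 participants;
a 14-day pre-quit phase in which every cigarette is logged (`smoke`
events); a 90-day post-quit phase with sparse lapses (about one per week)
and craving reports (level 1–5, a bit more than one per day, with at least
one report every day per the reporting protocol); sensors sampled 5 times
per minute, so 25 consecutive rows span exactly one 5-minute analysis
window; 5% of rows dropped as missing; and 3 of 17 participants reporting
nothing after quitting. Craving levels default to a mildly centre-heavy
distribution `(0.15, 0.20, 0.25, 0.20, 0.20)` — the protocol elicits both
routine daily reports (low levels) and acute-urge reports (high levels),
and nothing in the emulated design justifies a strongly skewed choice.

## Signal structure

Baseline inertial channels are stationary AR(1) noise (lag-1 correlation
0.8, unit marginal variance) — coloured enough to be non-trivial, simple
enough to reason about. Ambient light follows a day/night curve with
multiplicative log-normal noise; the time-of-day channel is minutes since
midnight scaled to `[0, 1)`. The midnight wrap-around discontinuity is
accepted: time of day is a weak covariate by design, and a circular
encoding would spend two channels on it.

Real data give no description of what the predictive pre-event movement
pattern *is* — only evidence that one exists. The generator therefore
plants a minimal, explicit motif in the `pre_event_window` (default 5
minutes) before each event timestamp, on the nine inertial channels:

* a sinusoidal burst with period `burst_period` (default 3 s), a proxy for
  a repetitive hand-to-mouth cadence, with axis-specific phase offsets;
* additive white noise that inflates high-frequency variance by
  `variance_gain` (default 3) at unit amplitude.

Both terms scale with `motif_amplitude`, so amplitude 0 produces label
structure with *no* signal — the null configuration used for chance-level
calibration. The motif is cohort-shared but jittered per participant: a
log-normal amplitude multiplier with log-sd `subject_jitter` and a
participant-specific burst phase, drawn once per participant. This makes
within-subject learning easy, cross-subject (LOPO) learning possible, and
the gap between them controllable.

Each event additionally draws its own random split of involvement across
the three sensors (a unit-mean Dirichlet-like weight triple from
normalised Gamma(0.7) draws). Movements differ between occasions, and no
single sensor observes every event at full strength; this is exactly the
structure under which the combined 9-channel ACC-GYR-MAG input carries
more evidence than any single sensor — the cross-sensor property the
evaluation is meant to detect. Without it, each sensor alone would be a
complete witness of every event and combining sensors could only add
noise.

Event times are homogeneous Poisson within waking hours (07:00–23:00),
rounded to whole seconds so logs survive text round-trips exactly. Whether
the real signature precedes, spans, or follows events is unknowable from
aggregate accuracy numbers; the generator defaults to "precedes". A
consequence worth knowing: a motif preceding an event near the start of a
window spills into the *previous* (negative) window, so a fraction of
negatives are contaminated — deliberate realism that caps attainable
accuracy slightly below 1 and gives the noise-removal rule something to
do.

Determinism: every participant's realisation is a pure function of
`(seed, participant_id)`, via a string-hash child-seed scheme; cohorts,
balancing, splits, and training all take explicit seeds derived the same
way.

## What the generator does not emulate

No gravity decomposition or sensor-fusion physics; no realistic activity
regimes (sleep/walk/drive); no device placement effects; no label noise in
event logs; missingness is independent per row rather than bursty. Passing
tests therefore show that the pipeline and models recover the signal the
generator plants under the stated conditions — not that real smoking
lapses are predictable at any particular accuracy. The printed accuracies
of the motivating analysis depend on an unreleased cohort and are not
reproduction targets here.

# The preprocessing pipeline

* **Slicing** — consecutive, non-overlapping 25-row windows aligned to the
  stream start; a trailing remainder is dropped. Clock alignment would
  change nothing contractual, so the simpler choice wins.
* **Missingness** — windows with a majority (≥ 13 of 25) of rows missing
  are removed; surviving gaps are filled by last-observation-carried-
  forward within the window (leading edge back-filled), so no values leak
  across window boundaries.
* **Labeling** — a window is positive iff an event falls in its half-open
  `[start, start + 5 min)` interval, which partitions time exactly; the
  earliest contained event donates kind and craving level (a deterministic
  tie-break for multi-event windows).
* **Noise-removal + balancing** — the published description of
  downsampling "with noise removal" is not operationally specified, so the
  package commits to a concrete, seedable rule: majority-class windows
  above the 95th percentile of mean within-window channel variance are
  excluded, then the remainder is sampled without replacement down to the
  minority count. Exact class equality is guaranteed and tested.
* **Splitting** — windows are shuffled before the 90/10 split (the
  non-overlapping slicing order is temporal, so shuffling avoids temporal
  leakage into the split), per participant, stratified by label.
* **Phase 2 binary labels** — craving reports of *every* level count as
  positive: even a level-1 report marks a moment when the smoker was
  thinking about smoking. The `lapse_vs_craving` reclassification keeps
  the split analyses possible.

# The models

Four architectures share a three-layer dense head (64 → 32 → 1, ReLU then
sigmoid) and differ in their encoder: LSTM, BiLSTM, 1D-CNN, and the
stacked 1D-CNN-BiLSTM. All are implemented directly in R with
BLAS-backed matrix operations — forward passes, backpropagation (through
time), batch normalisation, Adam — because the model equations are the
substance of the package, and every operator is validated against
independent brute-force references (triple-loop convolution, scalar
gate-by-gate recurrence) and finite-difference gradients.

Choices where the published description is incomplete or ambiguous:

* **Kernel span 11** — the convolution is written over `x_{i-10:i}`, an
  11-row receptive field. Exposed as `kernel_span` rather than hard-coded,
  since the index convention could also be read as 10 taps.
* **Cell-state recurrence** — the printed update
  `c_t = f_t * c~_{t-1} + i_t * c~_t` (previous *candidate*) would remove
  all long-range memory, contradicting the accompanying description of
  `c_t` as the state that "carries long-term information". The package
  uses the standard recurrence `c_t = f_t * c_{t-1} + i_t * c~_t`.
* **Batch-norm placement** — the "feature map output" of the conv layer is
  normalised, i.e. after ReLU, before pooling; per-filter statistics over
  batch × time, running means (momentum 0.9) at inference, eps `1e-5`.
* **Pooling** — "sliding" max window of size 3 read as stride 1.
  Tie-breaks in the pooling backward pass route gradient to the earliest
  maximal position.
* **Head input** — each direction's summary state: the forward stream at
  the last step and the backward stream at the first step (each has then
  consumed the whole sequence), concatenated to width `2 * hidden_size`.
  Hidden size defaults to 64, conventional for 25-step inputs.
* **Training** — Adam (lr `1e-3`, batch 32), binary cross-entropy plus the
  l2 penalty on conv kernels (`1e-4`), at most 100 epochs with early
  stopping (patience 10) on a stratified 10% validation split carved from
  the training data; best-epoch weights and batch-norm statistics are
  restored. Inputs are z-scored per channel with training-set statistics
  only. Glorot-uniform initialisation; LSTM forget-gate bias starts at 1.
  All of it is seeded; two runs with one seed produce identical weights.

# Evaluation designs

* **Within-subject** — balance one participant's Phase 1 windows, 90/10
  shuffled split, train, report on the 10%.
* **Phase transfer** — train on 100% of balanced Phase 1, test on Phase 2
  (balanced by default; a non-balanced mode keeps the natural imbalance,
  under which PPV/NPV are the informative summaries).
* **LOPO** — for each participant with Phase 2 reports, train on the
  pooled balanced Phase 1 windows of all others and score the held-out
  participant's Phase 2 windows; per-participant ROC/AUC, their
  unweighted mean, and lapse-only / craving-only splits. Train/test
  participant disjointness is machine-audited in the report.

Reports carry the confusion matrix (with accuracy, PPV and NPV; undefined
predictive values are reported as missing, never as 0), ROC points and
trapezoidal AUC (equal, by construction of the tie-grouped threshold
sweep, to the pairwise concordance probability), and accuracy stratified
by hour of day, event kind, and craving level.

`grid_experiment()` runs the full input-type × architecture grid
(6 × 4 cells), averaging accuracy over participants *unweighted* — the
design trains per participant, so each participant is one experimental
unit; a pooled variant would silently weight by recording length. The
Friedman rank test compares input types across participants as blocks,
with `Q = 12n/(k(k+1)) * sum_j (Rbar_j - (k+1)/2)^2`, `df = k - 1`, and a
chi-square tail p-value, reported at both alpha = 0.05 and 0.01. (A
published degrees-of-freedom value of 65 for a 4- or 6-level comparison is
not derivable from any block/treatment structure of this design; the
package reports the textbook `k - 1`.)

# Problem sizes in the shipped tests

The test-suite and acceptance-script experiments run scaled-down versions
of the study conditions, chosen so each check measures what it claims with
useful statistical resolution: a 12-day single participant with ~300
events (balanced to ~560 windows, 56 held out) for within-subject
recovery; a 6-participant, 6-day-per-phase cohort with low jitter (0.05)
for LOPO; models at 32 filters / 16 hidden units / 25–40 epochs. At motif
amplitude 2 these recover the signal essentially perfectly; at amplitude 0
they sit at chance; the amplitude sweep `{0, 0.5, 2}` spaces the
intermediate point far from both endpoints so the monotonicity checks are
not decided by training noise.

# Known limitations

Training is CPU-bound, full-precision, single-threaded R; it is sized for
cohorts of thousands of windows, not millions. No hyperparameter search,
attention variants, calibration analysis, or post-hoc pairwise tests are
included. GPS is excluded by design. The synthetic missingness and
activity models are intentionally simple; transferring conclusions to real
cohorts requires real data.
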