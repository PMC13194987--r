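# smokesense

Passive smartphone sensing for just-in-time smoking-cessation support.

`smokesense` is an R package for testing whether the movement signature a
smartphone records in the minutes before a smoking-related event —
accelerometer (ACC), gyroscope (GYR) and magnetometer (MAG) triaxial
streams, plus ambient light (L) and time of day (T) — can predict smoking
events before a quit attempt, and lapses and craving reports (level 1, very
low, to 5, very high) after it, inside a 5-minute window. A 5-minute
horizon is short enough to trigger a just-in-time adaptive intervention at
the moment of need.

The package is aimed at researchers in digital phenotyping and mHealth who
want a fully reproducible, self-contained version of this analysis: because
real cohorts of this kind are not openly released, it ships a synthetic
cohort generator that emulates the study design (a 2-week pre-quit phase
with logged cigarettes and a 3-month post-quit phase with logged lapses and
craving reports, sensors sampled 5 times per minute), so every stage of the
pipeline is testable end to end.

## What it contains

* **Synthetic cohorts** (`cohort_config()`, `motif_spec()`,
  `generate_cohort()`): AR(1) baseline inertial noise, diurnal light and
  time-of-day channels, Poisson event schedules in waking hours, per-row
  missingness, and a cohort-shared pre-event movement motif (a sinusoidal
  hand-to-mouth cadence plus high-frequency variance inflation) with
  per-participant amplitude/phase jitter and per-event sensor involvement.
* **Windowing pipeline** (`slice_windows()`, `drop_incomplete()`,
  `label_windows()`, `balance_downsample()`, `select_channels()`,
  `shuffle_split()`): non-overlapping 25-row (5-minute) windows,
  majority-missing removal, 0/1 event labeling, noise-filtered random
  downsampling to exact class balance, and seeded shuffled 90/10 splits.
* **Four sequence classifiers** (`model_config()`, `build_model()`,
  `train_model()`): LSTM, 1D-CNN, BiLSTM, and the stacked 1D-CNN-BiLSTM,
  implemented from first principles (forward passes, backpropagation
  through time, batch normalisation, Adam, early stopping) with no deep
  learning framework dependency. The core model is

  * a valid 1-D convolution over the 25-row window,
    `C_i = ReLU(w^T x_{i-10:i} + b)`, 128 filters, l2-regularised,
  * batch normalisation, then a sliding max-pool `P_i = max(C_{i:i+2})`,
  * a bidirectional LSTM — gates
    `f_t, i_t, o_t = sigmoid(W [h_{t-1}, x_t] + b)`,
    candidate `tanh(W_c [h_{t-1}, x_t] + b_c)`,
    cell state `c_t = f_t * c_{t-1} + i_t * c~_t`,
    hidden state `h_t = o_t * tanh(c_t)` — run in both directions and
    concatenated, `h_t = [h_t(fwd), h_t(bwd)]`,
  * a three-layer dense head ending in a sigmoid probability of an event
    in the window.
* **Evaluation harnesses** (`within_subject_eval()`,
  `phase_transfer_eval()`, `lopo_eval()`, `grid_experiment()`): the
  within-subject 90/10 design, the train-on-pre-quit / test-on-post-quit
  transfer design, and leave-one-participant-out (LOPO) cross-subject
  validation, with confusion matrices, PPV/NPV, ROC/AUC, hour-of-day and
  craving-level stratification, lapse-vs-craving splits, and the Friedman
  rank test (`friedman_rank_test()`) comparing classifiers across sensor
  input types.

## Worked example

Generate one participant with a strong pre-event motif, then train and
evaluate the 1D-CNN-BiLSTM on their pre-quit data:

```r
library(smokesense)

cfg <- cohort_config(n_participants = 1, phase1_days = 12, phase2_days = 6,
                     smokes_per_day = 25, motif_amplitude = 2,
                     subject_jitter = 0.1, seed = 101)
bundle <- generate_participant(cfg, motif_spec(), "P01")
bundle
#> Participant P01: 86400 Phase 1 rows / 297 smoke events; 43200 Phase 2 rows / 8 reports

rep <- within_subject_eval(bundle, arch = "1dcnn-bilstm",
                           channels = "ACC-GYR-MAG", seed = 17,
                           model_options = list(n_filters = 32, hidden_size = 16,
                                                dense_sizes = c(32L, 16L, 1L),
                                                epochs = 40, patience = 8))
rep
#> Evaluation report [within_subject] 1DCNN-BILSTM / ACC-GYR-MAG
#>   n = 56, accuracy = 1.000, AUC = 1.000
#>   confusion TP 28 FP 0 TN 28 FN 0; PPV 1.000 NPV 1.000
```

The report says: of the balanced Phase 1 windows held out for testing (28
event windows, 28 non-event windows), every one was classified correctly —
the planted motif at amplitude 2 is fully recoverable. With
`motif_amplitude = 0` the same pipeline returns chance-level accuracy
(≈ 0.5), confirming that the classifier finds signal only when the
generator plants one.

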