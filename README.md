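# cgtnet

Patient-specific seizure prediction from multichannel scalp EEG: an R
implementation of a complete prediction pipeline built around CGTNet, a
hybrid sequence classifier that combines parallel multi-scale 1-D
convolution, a gated recurrent unit and a sparse-masked Transformer
encoder.

The package is written for researchers in biomedical signal processing who
want an inspectable, fully testable version of this class of model: every
stage — from EDF input to the clinical alarm policy — is exposed as a
plain R function, all network gradients are hand-derived (and verified
against numerical differentiation in the test suite), and a seeded
synthetic-EEG generator with planted preictal signatures makes the whole
pipeline runnable end-to-end with no clinical data.

## The task and the model

EEG before a seizure (the **preictal** state, minutes to tens of minutes
ahead of onset) differs subtly from baseline **interictal** activity,
notably in theta (4–7 Hz) and alpha (8–12 Hz) band power and inter-channel
synchronisation. The pipeline classifies 64 s windows (32 s step) as
preictal vs interictal:

1. **Preprocessing** — 1 Hz high-pass and 60–65 / 120–125 Hz band-stop
   filtering (zero-phase Butterworth), resampling to 256 Hz, sliding-window
   segmentation and STFT spectrograms
   `STFT(t,f) = ∫ x(τ) h(τ−t) e^{−j2πfτ} dτ`.
2. **Features** — per window, 64 one-second frames × 34 frequency bands of
   channel-averaged log band power (a 2176-dim input); a factor-analysis
   path (maximum likelihood, Kaiser criterion eigenvalue > 1, capped at 64
   factors, label-relevance screening) provides the classical reduction.
3. **CGTNet** — two parallel convolution branches with kernels 62 and 32
   (`F = (n−1)s + k` receptive fields), each conv→BN→ReLU twice; a 128-unit
   GRU with gates
   `R_t = σ(W_r x_t + U_r h_{t−1} + b_r)`,
   `Z_t = σ(W_z x_t + U_z h_{t−1} + b_z)`,
   `h_t = (1−Z_t)⊙h_{t−1} + Z_t⊙tanh(W_h x_t + R_t⊙(U_h h_{t−1} + b_h))`;
   sinusoidal positional encoding; a 2-layer, 4-head encoder with sparse
   attention `softmax(QKᵀ/√d_k ⊙ M)V`, where the binary mask M (local +
   strided pattern, ≤ 32 nonzeros per row) cuts score evaluations from
   O(n²) to O(n·k); and a 2-logit head. The default configuration has
   exactly **550,978 trainable parameters**.
4. **Training / evaluation** — Adam (lr 1e-4), batch 64, sigmoid
   cross-entropy on logits with inverse-prevalence class weighting,
   per-patient stratified 5-fold cross-validation; accuracy, sensitivity,
   specificity, F1, MCC, AUROC, DeLong's test for correlated ROC curves,
   the Wilcoxon signed-rank test and Cohen's d.
5. **Alarm policy** — 0.5 probability threshold, three-consecutive-window
   confirmation, 30-minute refractory period, lead-time triage (< 5 min
   discarded, ≥ 20 min early warning) and false alarms per hour.

## Worked example

Generate a synthetic patient with a planted preictal signature, extract
labelled windows, train, and inspect the alarm chain:

```r
library(cgtnet)

cfg <- synth_config(n_channels = 8, duration_s = 7200,
                    seizure_onsets_s = 6000, theta_alpha_gain = 4, seed = 9)
rec <- generate_record(cfg)
rec
#> <eeg_record> patient SYN: 8 channels x 1843200 samples @ 256 Hz (7200.0 s), 1 seizure(s)

ds <- build_window_dataset(rec)          # filters, windows, labels, features
table(ds$y)
#>  0  1
#> 74 36

set.seed(1); tr <- sample(110, 88)       # hold out 22 windows
fit <- cgtnet_train(cgtnet_init(seed = 9), ds$x[tr, ], ds$y[tr],
                    train_config(epochs = 20, seed = 9))
round(fit$history[c(1, 10, 20)], 4)
#> [1] 1.5248 0.1493 0.0065

p <- cgtnet_predict(fit$model, ds$x[-tr, ])[, 2]
auroc(p, ds$y[-tr])
#> [1] 1
unlist(compute_metrics(confusion(p, ds$y[-tr])))
#> acc sen spe  f1 mcc
#>   1   1   1   1   1
```

The held-out windows separate perfectly: the planted 4× theta/alpha gain
is a strong signature, and 20 epochs of Adam at the default learning rate
drive the training loss from 1.52 to below 0.01. The alarm policy then
turns window probabilities into clinically shaped events:

```r
trace <- probability_trace(ds$start_s, cgtnet_predict(fit$model, ds$x)[, 2])
alarms <- raise_alarms(trace)            # >= 3 consecutive windows at p >= 0.5
score_alarms(alarms, onsets = 6000)$events
#>   time_s lead_time_s      category
#> 1   4928        1072  late_warning
```

The full desk-scale experiment (6 patients, 2 h each, per-patient 5-fold
cross-validation at 20 epochs) is one call:

```r
res <- run_cohort_experiment()
round(res$summary, 3)
#>   acc   sen   spe    f1   mcc auroc
#> 0.998 0.995 1.000 0.997 0.997 1.000
```

A command-line front end wrapping the same functions is installed at
`inst/cli/cgtnet.R`
(`Rscript cgtnet.R simulate|preprocess|train|evaluate|alarm ...`).

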