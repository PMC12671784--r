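---
title: "Methods: seizure prediction with multi-scale convolution, a GRU and a sparse Transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seizure prediction with multi-scale convolution, a GRU and a sparse Transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Seizure prediction asks whether the minutes-to-tens-of-minutes before a
seizure (the *preictal* state) can be distinguished from baseline activity
far from any seizure (the *interictal* state) in scalp EEG. `cgtnet`
implements a complete patient-specific pipeline for this binary
classification task — from EDF recordings and seizure annotations through
filtering, windowing, time–frequency features, a deep sequence classifier,
cross-validated evaluation, and finally a clinical alarm policy — together
with a seeded synthetic-EEG generator so that every stage can be exercised
and tested without access to clinical recordings.

## Preprocessing chain

Recordings are taken at (or resampled to) 256 Hz. The filter chain is a
1 Hz high-pass plus band-stops over 60–65 Hz and 120–125 Hz, removing drift,
power-line interference and its high-frequency image. The band edges are
fixed by the protocol; the realisation is ours: 4th-order Butterworth
designs applied forward–backward (`signal::filtfilt`), because zero-phase
filtering introduces no group delay and therefore cannot shift window
labels in time. Stop bands that would reach Nyquist (low-rate inputs) are
skipped with a warning rather than mis-designed.

Windows are 64 s long with a 32 s step on a fixed grid, half-open
`[start, start + 64)`; a record of duration `D` yields
`floor((D - 64)/32) + 1` windows. Each window is analysed with a short-time
Fourier transform. The protocol fixes the sampling rate and the outer
window; it does not fix the inner analysis segment, so we default to a 1 s
Hann taper (256 samples, 1 Hz resolution — the standard EEG choice) with
50% overlap for the general-purpose spectrogram, and verify a
Parseval-style energy identity in the tests.

Labelling: a window is preictal when it lies wholly inside the 20-minute
horizon before an onset (ending strictly before the onset), interictal when
its span is at least 60 minutes from every ictal interval. Windows
overlapping a seizure, straddling the horizon boundary, or falling between
the two zones are excluded rather than given ambiguous labels. Both the
horizon and the guard gap are configuration keys; 20 minutes matches the
early-warning criterion used by the alarm policy, and 60 minutes is a
deliberately conservative guard so that "interictal" really is baseline.

## Network input layout

The classifier takes one 2176-dimensional vector per window. The published
operating point fixes that number but not its decomposition, so the layout
is a configuration contract of this package: 64 one-second non-overlapping
STFT frames × 34 equal-width frequency bands (0–128 Hz) of channel-averaged
log10 band power. This preserves the time axis (needed by the convolution,
GRU and attention stages — 64 frames comfortably covers the largest
convolution kernel of 62) while compressing the frequency axis to a scale
where theta/alpha changes occupy distinct bands. Channel averaging keeps
the input layout independent of montage size; per-channel variants would
change the parameter count and are out of scope.

The factor-analysis module operates on a different view — per-window
frame-averaged spectrogram magnitudes concatenated over channels — because
its purpose is statistical (common factors across windows, Kaiser
retention, label-relevance screening), not sequence modelling. The two
views coexist deliberately; the sources that fix the 2176-dim input never
state how it would be derived from 64 retained factors, and we chose not to
invent a coupling the numbers do not support.

## The model

Two parallel 1-D convolution branches run over the 64-frame axis with the
34 bands as input channels: kernels 62 (macro-scale) and 32 (fine-scale),
each branch being conv(k, pad 0) → batch-norm → ReLU → conv(3, pad 1) →
batch-norm → ReLU. Branch outputs are aligned to a common 16-token sequence
by fixed linear interpolation of the time axis (a parameter-free pooling)
and projected per branch to 64 channels, so their concatenation is a
16 × 128 sequence.

A 128-unit GRU processes this sequence. Its gate equations are, with ⊙ the
Hadamard product and σ the logistic function:

* reset gate: `R_t = σ(W_r x_t + U_r h_{t-1} + b_r)`
* update gate: `Z_t = σ(W_z x_t + U_z h_{t-1} + b_z)`
* state: `h_t = (1 - Z_t) ⊙ h_{t-1} + Z_t ⊙ tanh(W_h x_t + R_t ⊙ (U_h h_{t-1} + b_h))`

Note two conventions that matter for exact reproduction: the candidate is
weighted by `Z_t` (not `1 - Z_t`), and the bias `b_h` sits inside the
reset-gated term. The test suite pins both against a scalar per-step
oracle.

Sinusoidal positional encodings are added after the GRU (learned
embeddings are deliberately not the default), and a 2-layer, 4-head
Transformer encoder with *sparse-masked* attention follows. Attention is
`softmax(Q K^T / sqrt(d_k))V` restricted by a binary admissibility matrix
M: inadmissible positions receive −∞ before the row softmax, i.e. they are
excluded, not zero-scored. A literal reading of "multiply the scores by M
inside the softmax" would give masked positions weight `exp(0)`; that
variant is available as `mask_semantics = "literal"` for comparison, but
exclusion is the default because the design intent is that the model attend
only to admissible positions. The default mask is the union of a local band
(half-width 8) and a stride-8 pattern, clipped to at most 32 nonzeros per
row keeping nearest keys first; the diagonal is always admissible, so no
row is empty. Score evaluations scale with the mask's nonzero count rather
than the squared sequence length, which the tests assert with an
instrumented counter.

Token mean-pooling and a 2-logit affine head finish the network. Training
minimises sigmoid cross-entropy on the preictal-minus-interictal logit
(equivalent to binary cross-entropy with logits on a single output);
reported probabilities come from the softmax over the two logits. The
positive class is weighted by inverse prevalence by default, since
interictal windows typically outnumber preictal ones.

### Parameter budget

The published operating point states 550,978 trainable parameters along
with the anchored hyperparameters (input 2176, kernels 62/32, GRU 128,
2 layers × 4 heads of width 32, 2 classes). Those anchors do not determine
the remaining widths, so we resolved them by constraint: an exhaustive
search over first-layer conv channels, second-layer conv channels and the
encoder feed-forward width for solutions matching the count exactly. The
frozen default is conv 52 → 32 channels per branch (the 32 echoing the
ambiguous "network size 32" setting), per-branch projection to 64, and
feed-forward width 268 (≈ 2 × the model dimension). `count_parameters()` on
the default configuration returns exactly 550,978, and the acceptance
script recomputes it at run time.

### Optimisation

Adam with learning rate 1e-4, batch size 64, 150 epochs and base seed 8 are
the protocol defaults (`train_config()`). Dropout (rate 0.3, a standard
value; the protocol names the technique but not the rate) is applied to the
attention and feed-forward outputs and the pooled representation. All
gradients — through the convolutions, batch-norm, the GRU recurrence, the
masked softmax and layer-norms — are hand-derived and verified against
central-difference numerical differentiation in the tests. Weights use
Glorot-uniform initialisation; feature standardisation statistics are
estimated on each training set and stored with the model. Batches are
shuffled with the run seed; per-fold seeds are derived as `seed + fold`, so
every experiment is bit-reproducible.

## Factor analysis

Features are standardised and the sample correlation matrix
eigen-decomposed; the number of common factors is the Kaiser count
(eigenvalues > 1) capped at 64 — the cap and the criterion are both part of
the stated protocol, and reconciling them this way ("Kaiser, at most 64")
is the only reading that honours both. Loadings are estimated by maximum
likelihood (`stats::factanal`, no rotation — rotation does not change the
retained subspace); when the ML surface is degenerate (near-singular
correlation matrices, Heywood cases, or more factors than the ML degrees of
freedom admit) the principal-axis solution from the same
eigen-decomposition is used, with a warning. Scores are regression
(Thomson) scores. Label relevance combines a point-biserial correlation
threshold (default 0.05) with a two-sample t-test at the 0.05 level, always
keeping at least the max-|r| factor; under the null this keeps a noise
factor with probability ≈ the test level, which the tests verify by
simulation.

## Alarm policy

Window probabilities are thresholded at 0.5 (boundary inclusive: a
probability of exactly 0.5 is preictal). An alarm requires three
consecutive suprathreshold windows and is timestamped at the *end* of the
confirming window (`start + 64 s`) — the earliest moment the decision is
available; a convention had to be chosen and all lead times use it
consistently. After an alarm, a 30-minute refractory period suppresses
further alarms and the confirmation count restarts. Alarms are scored
against the next onset: leads under 5 minutes are discarded (insufficient
intervention time), leads of 20 minutes or more within the association
horizon are early warnings, leads in between are late warnings (reported
separately, never counted as successes), and alarms with no onset within
the horizon (default 20 min + 30 min) are false alarms, reported per
interictal hour.

## The synthetic generator

`generate_record()` emulates the recording conditions the pipeline targets:
multichannel scalp EEG at 256 Hz with a 1/f background (slope β = 1), a
10 Hz alpha oscillator (0.3 × background RMS, per-channel phase), and a
60 Hz line tone at −20 dB so the band-stop filter has something real to
remove. Preictal minutes before each annotated onset carry the planted
signature the classifier must find: the 4–12 Hz content of the composite
signal is scaled so its band power is multiplied by `theta_alpha_gain`
(default 4), and a `sync_gain` fraction (default 0.5) of the background is
replaced by a source shared across channels, raising inter-channel
correlation. Seizures appear as 5 s spike-wave-like 3 Hz bursts.
Independent periodogram oracles verify in the tests that the planted
band-power ratio is ≥ 2 at gain 4, strictly increases with the gain, and
vanishes at gain 1; at `sync_gain = 1` the mean pairwise preictal
correlation exceeds 0.8.

What the generator does *not* emulate: real artifact families (EMG, eye
blinks, electrode pops), non-stationary background drift, patient
heterogeneity of spectra, or preictal signatures other than band-power and
synchrony changes. A model that passes the desk-scale experiment has
therefore demonstrated correct mechanics and the ability to recover a
planted spectral signature through the full pipeline — not clinical-grade
performance on hospital EEG.

## The desk-scale experiment

`run_cohort_experiment()` is the package's end-to-end study: 6 synthetic
patients, 2 h each with one seizure at 6000 s (so each record yields ~74
interictal and ~36 preictal windows), theta/alpha gain 4, base seed 8,
8 channels per record, per-patient stratified 5-fold cross-validation, and
a reduced budget of 20 epochs per fold. These sizes are the package's
chosen experiment scale: one seizure per 2 h record leaves a clean hour of
guard-gapped interictal baseline, and 20 epochs is where the training loss
on this cohort has long plateaued (the full protocol's 150 epochs change
nothing on synthetic data but multiply the runtime). The acceptance
checks require mean AUROC ≥ 0.90 and mean sensitivity ≥ 0.85 at the 0.5
threshold across the 30 patient × fold runs.

## Numerical choices and degenerate inputs

* EDF samples are quantised to 16 bits against each channel's physical
  range; round trips are exact to one quantisation step. Constant channels
  get a widened range to avoid zero division.
* `stft_spectrogram` rejects non-finite input; an all-zero window yields
  all-zero magnitudes (linearity includes zero).
* Metrics with zero denominators are reported as `NA` (undefined), never
  silently as 0; an all-zero confusion table is an error.
* The Wilcoxon test is exact for n ≤ 25 without ties, exact by full
  enumeration of sign assignments for n ≤ 14 with ties, and a
  continuity-corrected normal approximation otherwise.
* The DeLong comparison computes the structural-component variance of the
  paired AUC difference first; zero variance (e.g. identical score
  vectors) short-circuits to p = 1 with a degeneracy flag.
* Factor columns have their sign fixed (largest loading positive) so
  refits are identical, not merely sign-equivalent.
* Masked attention subtracts row maxima before exponentiation; rows always
  have at least the diagonal admissible.

## Known limitations

* Channel-averaged features discard topographic information; the channel
  saliency analyses possible with per-channel inputs are not reproducible
  here.
* The mutual-information motivation sometimes given for sparse attention
  budgets is not computed — only the per-row budget `k_max` is operational.
* Training is patient-specific; no cross-patient transfer is attempted.
* The EDF dialect is the 16-bit continuous-signal core; EDF+ annotation
  channels and discontinuous records are not parsed (annotations travel in
  CSV/JSON sidecars).
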