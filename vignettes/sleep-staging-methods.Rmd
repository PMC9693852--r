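---
title: "Methods: time-frequency imaging and CNN-BiLSTM sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-frequency imaging and CNN-BiLSTM sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical sleep scoring assigns one of five AASM stages (W, N1, N2, N3,
REM) to every 30-second epoch of an overnight polysomnogram.
`sleepstager` implements a single-channel-EEG scoring pipeline: epochs
are resampled to 256 Hz (7680 samples), band-limited to 0.3–35 Hz with
a zero-phase filter, converted to time–frequency images, and classified
by a convolutional network optionally followed by a two-layer
bidirectional LSTM. The design is one-to-one: one epoch in, one label
out, with no neighbouring-epoch context, which keeps the classifier
usable for online scoring.

Because clinical PSG corpora are access-restricted, the package ships a
synthetic polysomnography generator that reproduces the statistical
structure the pipeline relies on; every stage of the pipeline is tested
against it.

## Synthetic polysomnography

### Hypnogram model

The hypnogram is a first-order Markov chain over the five stages,
starting in W. Self-transition weights encode mean bout durations; the
off-diagonal routing follows the canonical cycle W → N1 → N2 → N3 → N2 →
REM → (W | N1). Two constraints calibrate the defaults:

* a full cycle averages ~105 minutes (90–120 min range), and
* the marginal stage fractions match the pooled clinical reference
  distribution returned by `stage_distribution_reference()`
  (W 24.6%, N1 15.1%, N2 42.5%, N3 7.2%, REM 10.7%; 72,496 epochs
  across 81 subjects).

Each stage's per-cycle dwell is split into about four bouts
(`bout_fragmentation = 4`), because real hypnograms are fragmented into
bouts of a few minutes rather than one uninterrupted block per stage
per cycle; this also shortens the chain's mixing time so empirical
marginals are stable at simulation scale. When `target_proportions`
is set, the transition matrix is recalibrated by iterative column
reweighting until its stationary distribution matches the target
(`calibrate_transition_matrix`), so the chain reproduces the clinical
imbalance exactly in expectation.

### Stage-conditional EEG

The clinical literature defines the stages by their dominant rhythms;
the generator realizes each as a narrowband oscillation with slow AM/FM
drift plus transient events, over a 1/f background 10 dB below the
rhythm:

| stage | rhythm | amplitude (pk-pk) | events |
|------|--------|--------------------|--------|
| W   | alpha 8–12 Hz | 10–40 µV | — |
| N1  | theta 4–7 Hz  | 10–40 µV | — |
| N2  | theta 4–7 Hz  | 20–60 µV | ~3 spindles (11–16 Hz, 20–40 µV), ~1 K-complex (≥75 µV, 0.5–0.8 s), ~1 sub-threshold slow wave (30–60 µV) |
| N3  | delta 0.5–2 Hz | 75–150 µV | — |
| REM | sawtooth trains 2–4 Hz | 10–40 µV | 6–8 trains of 2.5–4 s over a low mixed 5–11 Hz background |

All waveform-level parameters are artifact-defined (textbook AASM
ranges); no clinical dataset specifies a signal-level generative model.
The N2 slow waves deserve a note: AASM defines N2 as carrying *less
than 20%* slow-wave activity, so real N2 contains some delta. Including
it makes the N2/N3 boundary a continuum — the property that makes the
minority-class (N3) recovery genuinely dependent on how training
handles class imbalance, as in real data.

What the generator does *not* emulate: artifacts (movement, EMG
leakage, electrode pops), inter-subject variability, drifting
electrode impedance, apneas/arousals, and the intrinsic ambiguity of
transitional epochs. Passing the synthetic recovery suite therefore
shows the pipeline is *correctly implemented and able to learn
stage-conditional spectral signatures under clinical imbalance* — it
does not certify clinical accuracy.

## Preprocessing

Order: resample → band-pass → segment. Resampling is polyphase rational
resampling to 256 Hz (any input rate); the band-pass is a Butterworth
bandpass of order 4 realized as high-pass (0.3 Hz) and low-pass (35 Hz)
halves, each applied forward–backward (`signal::filtfilt`) for exactly
zero group delay. The cascade realization is numerically robust for the
very low 0.3 Hz edge at 256 Hz, where a direct transfer-function
bandpass is poorly conditioned. Epochs are half-open spans
`[i*7680, (i+1)*7680)` in 0-based sample coordinates; a trailing
partial epoch is dropped with a warning, and label/epoch count
mismatches are dropped-with-warning by default (`on_mismatch = "error"`
is available) — the clinical description does not state how unscored
epochs were handled, so the choice is exposed.

## Time-frequency imaging

### Fourier synchrosqueezing (FSST)

The STFT uses a Gaussian window (default length 257 samples ≈ 1 s at
256 Hz, hop 32). Writing `sigma_s` for the window's time standard
deviation in seconds, the half-power bandwidth used for the component
separation condition is `Delta = sqrt(2 ln 2) / gamma_g` with
`gamma_g = 2*pi*sigma_s`; two components are resolvable when separated
by `d = 2*Delta` (≈ 2.2 Hz at the default). The instantaneous-frequency
map is computed through the derivative-window STFT,
`omega_hat = eta - Im(V_g' / V_g) / (2*pi)`, masked where `|V|` falls
below a relative threshold. Each STFT coefficient is then reassigned
*along frequency only* (time is untouched, preserving causality) to the
bin nearest its `omega_hat`, scaled by `1/g(0)`.

One numerical decision matters here. Reassignment is a
permutation-with-merge: when several coefficients land on one target
bin, complex accumulation interferes and `sum |T|^2` cannot equal
`sum |V|^2` in general. The grid therefore carries both the complex
reassigned coefficients (the transform proper) and the reassigned
energy mass (`|V|^2` moved to target bins), on which per-frame energy
conservation holds to machine precision and which drives rendering.

### Morse-wavelet CWT

The scalogram uses the analytic generalized Morse wavelet with symmetry
`gamma = 3` and decay `beta = 20` (time-bandwidth product 60), 12
voices per octave, center frequencies covering 0.3–35 Hz (83 scales),
L2 normalization, FFT-based with circular boundary. Scale-to-frequency
mapping uses the wavelet's analytic peak frequency
`omega_p = (beta/gamma)^(1/gamma)`.

For batch imaging the CWT is evaluated on a time-decimated grid (every
30th sample, 256 columns) by alias-folding the spectrum before the
inverse FFT. The decimated columns are *exact* samples of the full
transform (verified to machine precision in the tests); a 224-pixel
image cannot resolve the full 7680-sample time axis anyway, so nothing
the renderer can see is lost, and imaging is ~6x faster.

### Rendering

Magnitude → `log1p` compression → per-image min–max to [0,1] → bilinear
resize to 224x224 → channel replication (a colormap is available but
grayscale replication is the deterministic default). Frequency is
cropped to 0.3–35 Hz with the highest frequency at image row 1. The
`log1p` step precedes min–max because EEG TF magnitudes span orders of
magnitude; plain min–max would saturate the image with the delta band.
An all-constant grid renders as an all-zero image with a warning.

## Classifiers

Two variants, mirroring a transfer-learning design where the
feature-extraction layers of a pretrained image CNN feed either a
softmax head or a recurrent head:

* `cnn`: backbone → dropout(0.5) → fully connected → softmax(5).
* `cnn_rnn`: backbone → sequence unfold/flatten → BiLSTM(128) →
  dropout(0.3) → BiLSTM(128) → dropout(0.3) → softmax(5).

The *compact* backbone (default, download-free) is a stride-4 stem
convolution followed by three conv+pool blocks, mapping 224x224x3 to a
7x7x64 feature map; `W_f = 7` columns form the sequence axis for the
recurrent head. A `pretrained-adapter` backbone slot exists for loading
an external network's feature-extraction layers from a checkpoint; it
is optional, and requesting it without weights errors with a pointer
back to the compact backbone. Backbone weights may be frozen
(`freeze_backbone = TRUE`) or fine-tuned at a reduced learning rate
(the default).

The LSTM recurrence is implemented explicitly (sigmoid gates, tanh
cell/output nonlinearities) and is checked element-by-element against a
scalar-loop oracle; the backward pass is plain BPTT, validated by
finite differences through the whole network. The BiLSTM summary
feeding the softmax is the concatenation of each direction's final
state (forward at t = T, backward at t = 1); the sequence ranges over
the *within-epoch* feature-map columns — the one-to-one reading of a
single-epoch classifier. An alternative reading (sequences over
successive epochs) exists but contradicts one-epoch-in/one-label-out
and is not implemented.

## Training

SGD with momentum 0.9 on softmax cross-entropy. Defaults: head learning
rate 1e-3, backbone 1e-4 (fine-tuning), batch 32, 20 epochs. Class
imbalance is addressed by random duplication oversampling (no synthetic
interpolation): minority classes are duplicated with replacement until
all counts match the majority, *inside the training portion only* —
splits and CV evaluation folds always keep the original distribution.
The 90/10 split is epoch-level (stratified by default, within one epoch
of the target fraction per class); a subject-wise split would be the
stricter design but the reference protocol splits epochs. All
randomness fans out from one seed through named substreams, so any run
is reconstructable from its config.

The synthetic-recovery study in the acceptance suite uses 2000 epochs,
CWT imaging, the `cnn_rnn` variant, and a desk-scale training
configuration (learning rate 5e-3 head / 1e-3 backbone, 4 training
epochs) chosen from a 400-epoch pilot: the synthetic classes are
learnable enough that longer schedules at the default rate only add
runtime. Those problem sizes keep the whole study at single-CPU desk
scale.

`kfold_cv()` partitions epochs into k folds (sizes within one), trains
on k−1 with the caller's training closure (where oversampling happens),
and evaluates on the held-out fold; `cv_summary()` reports per-class
mean and *population* standard deviation across folds (the reference
tables do not state which flavor; population is used and documented),
plus the unweighted across-class average of each metric column.

## Evaluation

`confusion_matrix()` (rows = truth), one-vs-all per-class sensitivity,
specificity, precision, F1 and accuracy in percent, and the overall
metrics: accuracy (trace/N), macro-F1, macro sensitivity and macro
specificity. Zero-denominator policy: a class never predicted has
undefined precision/F1, reported as `NA` in machine-readable output
with a warning and counted as 0 in macro averages. Reports print one
decimal; JSON keeps full precision.

## Numerical notes and limitations

* FSST assumes components separated by `d = 2*Delta`; closer components
  merge and the entropy-sharpening guarantee no longer applies.
* The CWT uses a circular boundary; coefficients within a wavelet
  support of the epoch edges wrap. Tests exclude an edge margin, and
  for 30-s epochs the affected fraction at sleep-relevant frequencies
  is small.
* The bilinear resize is a 2-tap interpolator; when downscaling the
  7680-column FSST grid it subsamples rather than averages. Rendering
  is deterministic either way, which is what the classifier contract
  requires.
* Ties in reassignment targets merge energy; ties in `classify_stages`
  resolve to the first class in stage order.
* Training the compact backbone from scratch at desk scale is not
  expected to reach clinical-corpus accuracy; the synthetic thresholds
  (macro-F1 ≥ 85%, per-class sensitivity ≥ 60%) are artifact-defined
  recovery criteria, not clinical claims.
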