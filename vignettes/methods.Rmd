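---
title: "Semi-supervised iEEG segment classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised iEEG segment classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical intracranial EEG (iEEG) review divides long single-channel
recordings into short windows (3 s here) that an expert assigns to one of
four categories: power-line noise (code 0), muscle artifact (1),
pathological activity containing interictal epileptiform discharges (IEDs)
and high-frequency oscillations (2), and physiological background (3).
Expert labels are scarce; unlabeled segments are abundant. `ieegsift`
implements a semi-supervised pipeline for exactly this regime:

1. every segment is converted to a normalized time-frequency tensor,
2. a recurrent sequence autoencoder is trained **without labels** to embed
   segments in a low-dimensional space (default 128 dimensions),
3. a small budget of N gold-standard labels per class fits one kernel
   density estimate (KDE) per class in the embedding space, and
4. new segments are classified by the class with the highest
   prior-weighted density — a Naive Bayes density classifier.

The package also ships a seeded synthetic generator of the four segment
classes, so every stage is testable end to end without clinical data, and a
pseudo-prospective mode that screens a long recording in which IED segments
are rare among physiological ones.

## Spectrogram tensors

`build_tensor()` computes a short-time Fourier magnitude with Hann windows
(window 256 samples, hop 128 — 50% overlap), applies `log(1 + m)`, and
stacks two channels: the row-normalized (per frequency bin, across time)
and column-normalized (per time frame, across frequency) z-scored
matrices, giving a `[2, F, T]` tensor with `F = window/2 + 1` and
`T = floor((L - window)/hop) + 1`. Choices worth knowing:

- **Hann window**: standard leakage control; the frame layout discards a
  trailing partial frame.
- **`log(1 + m)` by default**: compresses the dynamic range between mains
  peaks and background; raw-magnitude mode is a config flag
  (`log_transform = FALSE`) since whether magnitude, power or log power is
  normalized is a free choice of the representation.
- **Unit-RMS amplitude normalization before the STFT** (`amplitude_norm`,
  default on): removes acquisition-gain differences between channels and
  makes the tensor exactly invariant to rescaling the input — without it,
  the log transform breaks scale invariance in near-zero magnitude bins.
- **Population (divide-by-n) standard deviations** in all z-scores, with an
  `eps = 1e-8` guard: zero-variance slices map to all-zeros.

## The temporal autoencoder

The encoder is a single-layer GRU that consumes the tensor as a sequence of
`T` frames (each frame is the 2F-long concatenation of both channels at one
time step). An affine head maps the encoder state to the embedding. The
decoder is a GRU initialized from the embedding through a learned affine
map; at each step it receives the previous frame (the true frame during
training — teacher forcing — and its own previous output at inference)
together with an attention context, a softmax-weighted convex combination
of the encoder's per-step states. Luong dot-product attention is the
default; additive (Bahdanau) attention is selectable. A linear layer on
`[decoder state; context]` emits each reconstructed frame, and training
minimizes reconstruction MSE with Adam (learning rate 1e-3, batch 128,
10 epochs by default). After each epoch the mean cosine similarity between
validation tensors and their free-running reconstructions is recorded; the
returned model is the epoch with the highest validation cosine.

All forward and backward passes are implemented directly in R matrix
algebra; the analytic gradients of every parameter (both attention forms,
both pooling modes) are verified against central finite differences in the
test suite.

Design choices where the architecture was genuinely open:

- **Attention form.** For recurrent sequence reconstruction both
  dot-product (Luong) and additive (Bahdanau) decoder-over-encoder
  attention are standard; the dot-product form is the default for its
  simplicity, with the additive form selectable.
- **Embedding pooling** (`embedding_pool`). The default maps the *final*
  encoder state to the embedding. A `"mean"` mode pools the time-average of
  all encoder states instead; brief transients (a 50 ms discharge in a 3 s
  window) otherwise fade from the recurrent state before the sequence ends.
  The end-to-end study runs use mean pooling for exactly that reason (worth
  about 5 AUROC points on the pathological-vs-physiological pair at desk
  scale). An elementwise-max mode exists but measures clearly worse — GRU
  hidden units are not per-feature detectors, so their pointwise maximum is
  not a meaningful summary.
- **Gradient clipping** (`clip_norm`, default 5): the standard stabilizer
  for recurrent training. At desk scale it is decisive — without it,
  otherwise identical runs vary by up to 10 AUROC points on the hard class
  pair from occasional destabilizing updates.
- **Teacher forcing** during training, free-running at inference: the
  training signal stays well-conditioned while validation cosine measures
  the honest generative reconstruction.
- **Model selection**: best validation-cosine epoch within each training
  run. Selecting one shared model across cross-validation folds would leak
  information between folds, so each fold trains and selects its own.

## KDE Naive Bayes classification

Each class fits a product-of-univariate-Gaussians KDE on its N labeled
embeddings: per dimension `d`, Silverman's rule
`h_d = 0.9 min(sd_d, IQR_d/1.34) N^(-1/5)` (population sd, type-2 quantile
IQR), floored at `eps_bw = 1e-3` so degenerate dimensions stay usable. The
axis-aligned product kernel is the operational meaning of "Naive Bayes"
here and avoids the curse of dimensionality of a full multivariate KDE in
128 dimensions; a shared-scalar-bandwidth mode is selectable. Log densities
are computed with the log-sum-exp identity, so posteriors are exact and
finite even when all densities underflow; ties break toward the lowest
class code. Priors default to uniform (the protocol supplies equal N per
class) and are configurable for rare-event screening.

## The evaluation protocol

`make_folds()` assigns segments to k = 10 folds stratified by class
(per-fold class counts within one segment of even). For each fold,
`run_protocol()`:

1. holds the fold out as the test set;
2. divides the rest **label-blind** at random into 90% autoencoder
   training data and a 10% validation pool — the training split's labels
   are never read, which an audit trail records and the tests assert;
3. trains the autoencoder on the unlabeled training tensors;
4. draws N labeled embeddings per class from the validation pool (the only
   pre-test label access, logged as `vs_draw`) and fits the KDE classifier;
5. scores the test fold (logged as `test_scoring`) with one-vs-rest AUROC
   (Mann-Whitney concordance, ties at half credit), step-rule AUPRC
   (average precision), macro/weighted F1 and the confusion matrix.

Per-fold metrics aggregate as mean and standard deviation. Because the
label budget N only affects stage 4, `run_protocol(..., budgets = c(10,
100))` trains each fold's autoencoder once and re-fits the KDE stage per
budget — sweeping N re-fits only the classifier stage, never the encoder.

The 90/10 division is deliberately *not* stratified by class: stratifying
would require reading the labels of data whose labels the protocol promises
to discard. Consequently small smoke runs need a validation pool several
times N per class, or the N-per-class draw can fail with a labeled
shortfall error.

`pseudo_prospective_eval()` deploys a frozen model and classifier on a long
recording with binary labels (0 physiological, 1 IED) and scores each
segment by the posterior of the pathological class.

## The synthetic generator

`generate_segment()` emulates the four classes at desk scale (512 Hz by
default; 5 kHz reproduces the clinical 15,000-sample segments):

- **class 3** — pink (1/f) noise at 10 µV standard deviation plus a
  band-limited 8-12 Hz oscillation of matching amplitude;
- **class 2** — the *identical* class-3 background (same seed, same draws)
  plus 1-5 biphasic raised-cosine sharp waves (half-wave width 30-70 ms,
  peak 6x the background sd, random polarity and onset) and, when the
  Nyquist frequency allows, 1-3 Gabor-atom HFO bursts (80-200 Hz, 20 ms
  envelope, 2x background sd);
- **class 1** — pink noise plus 2-4 Hann-gated bursts (0.3-1 s) of >30 Hz
  high-passed white noise at +20 dB over background;
- **class 0** — a 50 Hz (or 60 Hz) sinusoid with 2nd/3rd harmonics at
  -10/-20 dB and pink noise 20 dB below the mains line.

Waveform shapes (raised cosine, Gabor atom, gated noise) are the simplest
parametric forms with the right time-frequency signatures; amplitudes and
rates are package choices of realistic magnitude, not estimates of any
clinical dataset. Per-segment seeds derive from `(master seed, index)`, so
datasets are reproducible under reordering. Class 2 sharing class 3's
background is intentional: the *only* separating evidence is the
graphoelements themselves, which is the clinically honest difficulty.

What the generator does **not** emulate: multi-channel spatial structure,
seizures, non-stationary background drift, electrode artifacts other than
EMG-like bursts, and real IED morphology variation. Passing tests therefore
demonstrate that the pipeline recovers known, well-posed class structure at
small scale — not clinical-grade performance.

A note on spectral fingerprints: the generator guarantees (and the tests
assert) that band-power ratios separate each signature class from the
classes lacking that signature — mains band for class 0, the >30 Hz band
for class 1 against classes 2/3, the oscillation band for class 3 against
classes 0/1. The >30 Hz ratio cannot separate artifact from power-line
segments, whose mains line also lies above 30 Hz; pairwise separability in
that literal sense is not a property of these band features.

## Problem sizes and numerical choices

The package's own study conditions (`study_config()`), used by the
acceptance script and the heavier tests, are chosen to exercise the full
pipeline at desk scale:

- spectrograms in raw-magnitude mode (`log_transform = FALSE`) with hop 64
  (75% overlap): the log transform compresses exactly the contrast that
  distinguishes brief 6-sigma discharges from background, and the finer hop
  localizes them in time;
- autoencoder: 8-dimensional embedding, 64 hidden units, 30 epochs, batch
  128, mean pooling, clipping at norm 5 — small codes keep the kernel
  density stage sample-efficient at N = 100, and moderate capacity encodes
  more into the embedding (large decoders reconstruct well through
  attention without enriching the code);
- end-to-end run: 512 Hz, 400 train / 100 validation / 100 test segments
  per class, label budget N = 100;
- budget sweep: 5 seeds, 150/110/60 segments per class per role, 8 epochs,
  N in {10, 100}, one autoencoder per seed;
- pseudo-prospective screen: a 30-minute recording (600 segments) with IED
  prevalence 0.1, screened by a deployed pipeline — the same pretrained
  autoencoder with the KDE stage re-fit on N = 500 labels per class. The
  budget experiments keep their stated N; deployment uses the best
  classifier the labeled pool supports, which is how a frozen screen would
  be shipped.

Other numerics: Adam moments (0.9, 0.999, eps 1e-8); uniform
`[-1/sqrt(H), 1/sqrt(H)]` weight initialization; softmax and log-density
computations shifted by the row maximum; KDE quadrature sanity checked to
integrate to 1; all RNG flows through explicit seeds (`withr::with_seed`),
leaving the caller's RNG state untouched.

## Projections for expert review

`project_2d()` maps embeddings to two dimensions for visual review via
Sammon's non-linear stress minimization (initialized from classical MDS),
or PCA. The projection is strictly for human inspection — no pipeline
decision consumes the coordinates — and `render_scatter()` writes labeled
scatter plots with the class legend in code order (binary IED legend in
pseudo-prospective mode). A rank-based trustworthiness statistic in the
tests checks that the mapping preserves high-dimensional neighborhoods
better than a random layout.

## Known limitations

- The autoencoder is plain R; it is comfortable at the desk scales above
  (seconds to a few minutes) but not meant for corpus-scale training.
- Single channel only; no EDF/BrainVision readers (the manifest + array
  container interface is the extension point).
- The KDE classifier inherits the embedding's geometry; if the encoder
  collapses two classes, no bandwidth choice recovers them.
- Synthetic validation bounds what can be claimed about clinical data; see
  the generator section above.
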