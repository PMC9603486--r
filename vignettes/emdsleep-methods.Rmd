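---
title: "Sleep staging with EMD features and stacked autoencoders: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging with EMD features and stacked autoencoders: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdsleep)
```

## The problem and the pipeline

Overnight polysomnography EEG is scored by experts into six
Rechtschaffen–Kales stages — wake (W), four NREM stages (S1–S4) and REM —
in 30-second windows. `emdsleep` automates that scoring for single-channel
EEG (typically Fpz–Cz or Pz–Oz at 100 Hz) with a four-stage pipeline:

1. **Segmentation** (`segment_epochs`): the recording is cut into
   consecutive 30-s epochs (3000 samples at 100 Hz); each epoch takes the
   hypnogram stage at its midpoint; Movement-Time and unscored epochs are
   excluded.
2. **Empirical mode decomposition** (`emd`): each epoch is sifted into up
   to 10 intrinsic mode functions (IMFs) plus a residue. EMD is fully
   data-driven and stays in the time domain, which suits the non-stationary,
   artifact-prone character of sleep EEG; discarding the leading
   (highest-frequency) modes is a simple, effective denoiser (`denoise`).
3. **Feature extraction** (`featurize_epochs`): eleven time-domain
   statistics per IMF — mean, standard deviation, RMS, peak-to-peak,
   skewness, margin factor, crest factor, impulse factor, square root of
   the magnitude (SRM), kurtosis value and kurtosis factor — concatenated
   into a 110-dimensional epoch descriptor.
4. **Stacked autoencoder classification** (`sae_fit`): greedily pretrained
   sigmoid autoencoders compress the descriptor (default 110 → 32 → 2); a
   softmax head on the terminal 2-D code assigns one of the six stages, and
   an end-to-end fine-tuning phase sharpens both. The 2-D code doubles as a
   visualizable "abstract feature pool" (`plot.sae`) in which the stages
   should form nearly disjoint clusters.

Evaluation (`eval_report`, `kfold_cv`, `compare_baselines`) reports
confusion matrices, per-class and average accuracy, stratified 10-fold
cross-validation, and comparisons against a feed-forward network, an RBF
SVM and a decision tree trained on the identical features.

## EMD: numerical choices

*Extrema.* Strict interior local extrema; a flat plateau contributes one
extremum at its midpoint (the lower middle index when the plateau has even
length). Endpoints are never extrema.

*Envelopes.* Natural cubic splines through the maxima (upper) and minima
(lower), with supports mirror-extended by two extrema across each end of
the signal. Mirror extension is the canonical guard against envelope
divergence at the boundaries; a `clamp` alternative is available.

*Sifting stop rule.* A candidate mode is accepted when the Cauchy-style
criterion `SD = sum(m^2) / sum(h^2) < 0.2` (with `m` the subtracted
envelope mean) **and** the IMF condition — extrema and zero-crossing counts
differ by at most one — hold simultaneously. The joint rule guarantees
every emitted mode is a bona fide IMF, not just a numerically converged
iterate. The iteration cap is 200: with the classical cap of 100, roughly
one epoch in a hundred emits a mode that satisfies the SD criterion but
still fails the IMF count condition; such modes typically need ~150 sifts.
The cap never raises an error — a capped mode is returned with
`stop_reason = "max_iters"` and recorded in the decomposition metadata.

*Decomposition stop.* Sifting of the running residue stops when the
residue is monotone or has a single hump (fewer than two maxima or two
minima), or when 10 IMFs have been extracted. Completeness —
`sum(IMFs) + residue == input` — holds to machine precision by
construction, because the residue is the literal remainder.

*Denoising.* `denoise(d, drop_first_k = 1)` discards IMF1, where broadband
artifact energy concentrates. The choice of one discarded mode is a
default, not a claim of optimality; it is exposed as a parameter, and the
test suite verifies that it raises the SNR of 2-Hz slow waves contaminated
at 0 dB in at least 90% of seeded trials.

## The eleven statistics

Definitions (per IMF, `N` samples): mean; standard deviation with the
`N - 1` divisor; `RMS = sqrt(mean(x^2))`; peak-to-peak `max - min`;
skewness and kurtosis as the third and fourth standardized moments (the
standard deviation, not the variance, standardizes — the dimensionally
consistent reading); `SRM = (mean(sqrt(|x|)))^2`; margin factor
`max|x| / SRM`; crest factor `max|x| / RMS`; impulse factor
`max|x| / mean|x|`; kurtosis factor `KV / (mean(x^2))^2`.

Degenerate inputs are mapped to exact zeros rather than NaN: a constant
signal zeroes the standardized moments, an all-zero signal additionally
zeroes the amplitude ratios; affected names are flagged in the
`"degenerate"` attribute. An independently written naive-loop oracle in
the test suite pins every formula.

When a decomposition yields fewer than 10 IMFs the missing feature blocks
are zero with their mask bits off, keeping the vector length fixed at 110.
The residue is excluded by default (`include_residue = FALSE`): it is a
trend, not a mode.

## Stacked autoencoder: architecture and training

Defaults: `hidden_sizes = c(32, 2)`, sigmoid activations everywhere,
mean-squared reconstruction loss for pretraining, cross-entropy for the
head and fine-tuning, plain mini-batch SGD (`learning_rate = 0.5`,
`batch_size = 32`, `l2_weight = 1e-5`), 60 pretraining epochs per layer,
200 head epochs, 300 fine-tuning epochs, and internal min–max scaling of
the inputs to [0, 1] (sigmoid decoders need bounded targets; the scaler is
fit on the training data only and stored in the model). An optional
KL-sparsity penalty is available but off by default. All randomness
(weight initialization, batch order) flows from one master seed through a
Lehmer-step seed derivation, so fits and predictions are bit-reproducible.

Design choices that were genuinely open:

- **Code dimension 2.** The terminal 2-D code is narrow for a six-class
  problem, but it is what makes the abstract pool directly plottable, and
  end-to-end fine-tuning makes it discriminative on well-separated data.
  For harder problems `head_from = "penultimate"` attaches the softmax to
  the 32-D code instead, and `finetune_epochs = 0` freezes the pretrained
  encoders.
- **Ties** in the softmax output resolve to the lowest class index
  (`which.max`), documented and deterministic.
- **Epochs are split individually** (60/40, `round` rule) by default;
  `split_by_recording = TRUE` in `split_train_test` gives the leakage-safe
  alternative where whole recordings stay on one side. Epoch-wise pooling
  is the default because whole-corpus segment counts divide exactly that
  way; recording-wise splitting is the right choice when estimating
  generalization to unseen subjects.

## What the synthetic generator does and does not emulate

`generate_dataset` emits 30-s, 100-Hz epochs as sums of band-limited
random-phase sinusoids plus burst transients and white noise, with
per-stage defaults: W desynchronized 4–30 Hz at low amplitude; S1 slow
2–7 Hz at the highest background amplitude (kept as the conventional
textbook description this package follows, although some scoring
literature associates 8–13 Hz alpha with drowsiness instead); S2 moderate
4–8 Hz background with 12–14 Hz spindle bursts; S3/S4 dominant ~2 Hz slow
waves with S4 carrying a larger delta fraction; REM mixed 2–30 Hz
low-amplitude activity with slow sawtooth bursts. Band amplitudes set the
band RMS to `amplitude / sqrt(2)`; the default amplitudes were fixed once,
at values giving clearly separable classes, and are not adjusted per
experiment. `contaminate` adds broadband Gaussian, power-line, baseline
drift or ocular-blink artifacts at an exactly achieved target SNR and
returns the clean reference for oracle use.

The generator is a test instrument, not a head model: it has no
stage-transition structure, no inter-subject variability, no 1/f
background, and its stages are far better separated than real scored EEG.
Passing the synthetic end-to-end bar therefore demonstrates that the
pipeline's machinery — decomposition, features, training, evaluation — is
correct and stable, **not** that the headline accuracy would transfer to a
real polysomnography corpus.

## Problem sizes used by the tests and the acceptance script

The default end-to-end experiment uses 200 epochs per class (1200 epochs,
720/480 train/test after the 60/40 split), chosen as the smallest corpus
at which the stacked autoencoder's advantage over the raw-feature
baselines is stable across seeds. The EMD completeness and denoising
properties are checked on ~100 epochs and 50 seeded trials respectively;
the corpus-geometry check segments full 20-hour synthetic recordings and
scales the per-recording epoch count to the 153-recording corpus. The
cross-validation report uses k = 10.

## Known limitations

- Plain EMD only — no ensemble variants (EEMD/CEEMDAN), so mode mixing on
  real EEG is possible; the feature layout tolerates it but accuracy may
  suffer.
- The EDF reader targets well-formed EDF/EDF+C single-rate signals; it
  does not handle discontinuous (EDF+D) files.
- Only EEG is used: no EOG/EMG fusion, no re-scoring of hypnograms.
- `kfold_cv` stratifies by epoch, not by recording; with few recordings
  per class, use the recording-wise splitter and construct folds manually.
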