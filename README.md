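# emdsleep

Automated sleep-stage classification for single-channel polysomnography
EEG, for sleep researchers and biomedical-signal engineers who want a
transparent, fully reproducible staging pipeline rather than a black box.

Expert scorers label overnight EEG in 30-second epochs as wake (W), NREM
stages S1–S4 or REM. `emdsleep` reproduces that decision chain
automatically:

1. **EDF input** — read EDF/EDF+ recordings (e.g. Fpz–Cz at 100 Hz) and
   hypnogram annotations, segment into labelled 30-s epochs (stage at the
   epoch midpoint; Movement-Time excluded), split 60/40 or into stratified
   k folds.
2. **Empirical mode decomposition** — each epoch x(t) is sifted into
   intrinsic mode functions, x(t) = Σᵢ IMFᵢ(t) + r(t), using natural
   cubic-spline envelopes with mirrored boundaries and a Cauchy stopping
   criterion (SD < 0.2) joined with the IMF extrema/zero-crossing
   condition. Dropping the leading modes denoises the epoch.
3. **Feature extraction** — 11 time-domain statistics per IMF (mean, σ,
   RMS, peak-to-peak, skewness SV = E[((x−x̄)/σ)³], margin factor
   max|x|/SRM with SRM = (E√|x|)², crest factor max|x|/RMS, impulse
   factor max|x|/E|x|, kurtosis value KV = E[((x−x̄)/σ)⁴], kurtosis
   factor KV/(E[x²])²), concatenated over 10 IMFs into a 110-dimensional
   descriptor.
4. **Stacked autoencoder** — greedy layerwise pretraining (110 → 32 → 2,
   sigmoid, mini-batch SGD), a softmax head on the 2-D "abstract feature
   pool", and end-to-end fine-tuning; evaluated by holdout and 10-fold CV
   against FFNN, SVM and decision-tree baselines on identical features.

A synthetic EEG generator with stage-specific spectral signatures
(S1 2–7 Hz, S2 12–14 Hz spindles, S3/S4 ~2 Hz slow waves, REM sawtooth
bursts, W desynchronized broadband) plus controllable artifact
contamination makes the whole pipeline testable without any data
download.

## Worked example

```r
library(emdsleep)

es <- generate_dataset(n_per_class = 50, seed = 42)   # 300 synthetic epochs
sp <- split_train_test(es, train_frac = 0.6, seed = 42)
fe_tr <- featurize_epochs(sp$train)                   # EMD + 11 stats per IMF
fe_te <- featurize_epochs(sp$test)
model <- sae_fit(fe_tr$X, fe_tr$stage, seed = 42)
eval_report(fe_te$stage, predict(model, fe_te$X))
```

```
<eval_report> n = 120, average accuracy = 0.9500
     predicted
true   W S1 S2 S3 S4 REM
  W   17  0  1  0  0   0
  S1   1 21  0  0  0   0
  S2   1  0 21  0  0   0
  S3   0  1  0 15  2   0
  S4   0  0  0  0 22   0
  REM  0  0  0  0  0  18
per-class accuracy: W 0.944, S1 0.955, S2 0.955, S3 0.833, S4 1.000, REM 1.000
```

120 held-out epochs were staged with 95% average accuracy
(trace/n of the confusion matrix); rows are the true stages, columns the
predictions, so the 2 in row S3 shows two deep-sleep epochs mistaken for
S4, the adjacent stage. Accuracy rises with the training budget — the
default experiment at 200 epochs/class is run by the acceptance script
below. `plot(model, fe_te$X, fe_te$stage)` draws the 2-D abstract feature
pool; `kfold_cv(...)` and `compare_baselines(...)` produce the
cross-validated and baseline-comparison reports.

A command-line front end wrapping these functions is installed at
`inst/cli/emdsleep.R` (subcommands `synth`, `segment`, `featurize`,
`train`, `predict`, `evaluate`).

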