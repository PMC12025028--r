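# emgmixer

Granular surface-EMG gesture recognition with a ConvMixer classifier and
handcrafted-feature fusion.

## The problem

Rehabilitation tasks such as pouring from a bottle involve subtle, graded
forearm activity: the same pouring *direction* (left, right, front) can be
executed at different wrist *angles* (22.5°, 45°, 67.5°, 90°), and a
recognition system for prosthetics or therapy monitoring must resolve both.
`emgmixer` implements a complete offline pipeline for this problem on
4-channel surface electromyography (sEMG):

1. **Synthetic session generator** — protocol-faithful multichannel sEMG
   (band-limited noise carriers with direction-dependent channel gains and
   monotone angle-dependent amplitude, trapezoidal onset/offset ramps, 50 Hz
   powerline interference, baseline noise), so the whole pipeline is testable
   without access-restricted clinical recordings.
2. **Preprocessing** — zero-phase 50 Hz notch and 20–450 Hz Butterworth
   band-pass, then segmentation into 250 ms windows with a 50 ms step
   (80 % overlap; at 1925.9259 Hz each window holds 481 samples).
3. **Time-domain features** per channel per window:
   - root mean square `RMS = sqrt( (1/N) Σ xᵢ² )`
   - sum-of-squares power `VAR = (1/(N−1)) Σ xᵢ²`
   - thresholded zero crossings `ZC = Σ sgn(−xᵢ·xᵢ₊₁)`, `sgn(u)=1` iff `u > ε`
   - waveform length `WL = Σ |xᵢ₊₁ − xᵢ|`

   giving a 16-dimensional vector (4 features × 4 channels).
4. **Granular label system** — three granularity levels over the gesture
   taxonomy: `coarse` (4 primary categories: left / right / front / hold),
   `granular2` (7 classes: two angle groups per direction + hold) and
   `granular1` (13 classes: every direction × angle + hold), with a
   coarsening function mapping subclasses back to primary categories and a
   probability-mass coarsener for model outputs.
5. **ConvMixer classifier** (implemented from scratch, analytic backprop,
   Adam): patch embedding by a strided 2-D convolution spanning all 4
   electrode channels, mixer blocks of depthwise (spatial-mixing) and
   pointwise (channel-mixing) convolutions — each followed by GELU and batch
   normalisation `Y = (X − μ)/√(σ² + ε) · γ + β` — global average pooling,
   and optional *late fusion*: the standardised 16-dim feature vector is
   concatenated with the pooled embedding before the linear classifier.
6. **Evaluation** — confusion matrices at any granularity; accuracy,
   macro one-vs-rest sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`;
   SVM / random-forest / LDA feature-only baselines.

## Worked example

```r
library(emgmixer)

cfg <- pipeline_config(
  repetitions = 3,                      # 3 repetitions of each gesture
  level = "granular1",                  # train at the 13-class fine level
  fusion_mode = "late_concat",          # fuse handcrafted features
  model = list(hidden_dim = 32, depth = 2, epochs = 12, batch_size = 96),
  seed = 1)
res <- run_pipeline(cfg, out_dir = "run1")

res$fine
#> eval_report (13 classes, n = 799): accuracy 0.9662, macro sensitivity 0.9636, macro specificity 0.9972
res$coarse
#> eval_report (4 classes, n = 799): accuracy 1.0000, macro sensitivity 1.0000, macro specificity 1.0000
res$baselines$svm
#> eval_report (13 classes, n = 799): accuracy 0.9850, macro sensitivity 0.9838, macro specificity 0.9988
```

The pipeline generated 42 trials (12 direction × angle gestures + 2 hold
trials, 3 repetitions, 5 s active / 5 s rest each), filtered them, cut 4,032
overlapping windows, and trained a fused ConvMixer on a stratified 60/20/20
split. The fine report shows that the 13 angle-resolved subclasses are
recovered at ~0.97 held-out accuracy; the coarse report shows that after
probability-mass coarsening, *all* residual confusions lie between adjacent
angles of the same pouring direction, so the 4 primary categories are
recovered perfectly. That ordering — errors confined within direction
granules, vanishing under coarsening — is the behaviour the granular label
design is built around.

A command-line front end over the same functions is installed at
`inst/cli/emgmixer.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/emgmixer.R", package="emgmixer"))')" \
  pipeline --seed 1 --out run1
```

with subcommands `generate`, `preprocess`, `featurize`, `train`, `evaluate`,
`pipeline` and `compare`.

## Limitations

The synthetic generator reproduces the *geometry* of the task (channel
layout, angle grading, timing, interference), not the physiological
difficulty of real sEMG; accuracies on synthetic sessions are upper bounds,
and the package makes no claims about clinical data. See the methods
vignette (`vignettes/emgmixer-methods.Rmd`) for the full model description,
parameter choices and known limitations.
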