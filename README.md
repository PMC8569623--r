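# semgesture

Dynamic hand-gesture recognition from multichannel surface electromyography
(sEMG) fused with a tri-axial accelerometer (ACC), in pure R.

Surface EMG measured by a forearm electrode cuff carries a spatial pattern
of muscle activation that identifies a hand movement; for *dynamic*
gestures the pattern also evolves in time. `semgesture` implements a
complete decoding pipeline for this problem:

* **Signal conditioning** — active-segment extraction by thresholding the
  multi-channel energy `S(n) = sum_c (x_c(n) - mean_c)^2` at 15% of its
  peak; power-line removal with a 20-notch IIR comb at 50 Hz and
  harmonics; wavelet denoising (`coif5`, SURE threshold, hard
  thresholding).
* **Image construction** — sliding-window sEMG images and 4 x C feature
  images with per-channel MAV, FR, MDF and MNP; mutual-information
  recursive feature ranking.
* **The classifier** — a multi-stream network: the input image is split
  into n equal patches, one electrode group per stream, and each stream
  applies residual units with
  squeeze-and-excitation recalibration (`y = x + SE(F(x))`) built from
  channel-shuffled grouped pointwise convolutions; streams are fused and
  integrated over time by a **Variant ConvLSTM** whose gates act on
  globally pooled channel descriptors,

  ```
  f_t = sigmoid(W_fh GP(H_{t-1}) + W_fx GP(X_t) + b_f)        (FC, pooled)
  C_t = f_t o C_{t-1} + i_t o tanh(W_ch * H_{t-1} + W_cx * X_t + b_c)
  H_t = o_t o tanh(C_t)                                       (* = conv)
  ```

  keeping convolution only on the candidate path — strictly fewer
  parameters than a full ConvLSTM at matched sizes. The ACC joins as an
  independent two-layer branch before the softmax classifier head.
* **Training and evaluation** — a seeded Adam training loop with
  stratified validation, accuracy / per-class recall / confusion metrics,
  and the four-way ablation (single vs. multi stream, raw vs. feature
  image, with/without ACC).
* **A synthetic generator** — the acquisition protocol this method targets
  (16 channels at 1000 Hz, six gestures, rest/action cycles) has no public
  dataset, so the package ships a seeded simulator with per-gesture
  spatial gain and spectral signatures, mains interference and
  gesture-correlated ACC trajectories. All experiments in the tests run on
  it; see the methods vignette for what it does and does not emulate.

The neural network, including every backward pass, is implemented in base
R (no external deep-learning framework) and is sized for desk-scale
experiments.

## Worked example

```r
library(semgesture)

# simulate a small labelled dataset: 6 gestures, 2 s trials (1 s rest +
# 1 s action), 16 channels at 1000 Hz, 15 dB action-to-rest SNR
ds <- generate_dataset(n_train_per_class = 20, n_test_per_class = 8,
                       n_classes = 6, fs = 1000,
                       cfg = noise_config(snr_db = 15, seed = 42),
                       duration_s = 2)

# condition one recording and find its active segment
rec <- preprocess_recording(ds$train$recordings[[1]])
detect_active_segments(rec)
#>   start  end peak_energy
#> 1  1037 2000  0.01306311

# feature image of one 200 ms window inside the segment
w <- window_signal(rec$semg[, 1038:2000], 200, 100)[[1]]
signif(build_feature_image(w, fs = 1000)[, 1:4], 3)
#>         [,1]     [,2]     [,3]     [,4]
#> MAV 1.39e-02 2.31e-02 1.41e-02 1.94e-02
#> FR  7.57e-02 4.85e-02 3.46e-02 5.47e-02
#> MDF 1.35e+02 2.40e+02 2.70e+02 3.25e+02
#> MNP 3.09e-06 8.67e-06 3.15e-06 6.29e-06

# train the multi-stream feature+ACC model (reduced widths) and evaluate
mcfg <- model_config(mode = "feature", streams = 4, widths = c(8, 8, 8),
                     lstm_hidden = 8, fc_dim = 32, n_classes = 6)
tr <- prepare_model_inputs(ds$train, mcfg)
te <- prepare_model_inputs(ds$test, mcfg, norm_stats = tr$norm_stats)
fit <- train_model(init_model(mcfg, seed = 1), tr,
                   train_config(batch_size = 16, epochs = 12, lr = 1e-2,
                                seed = 1))
evaluate_model(fit$model, te)
#> <semg_metrics> accuracy 1.0000 on 48 samples
```

The detected segment starts at sample 1037 — the rest/action boundary is
at sample 1000, plus the 100 ms onset ramp — and the MAV and MDF rows of
the feature image reflect the gesture's per-channel amplitude and spectral
signatures; training on 120 recordings separates the six synthetic
gestures completely at this SNR.

A thin command-line front end over the same functions is installed at
`inst/cli/semg` (subcommands `simulate`, `preprocess`, `featurize`,
`train`, `evaluate`, `ablation`, `summary`), e.g.

```sh
Rscript inst/cli/semg simulate --out data --train 20 --test 5 --seed 1
Rscript inst/cli/semg train --data data --out model.rds --epochs 12
Rscript inst/cli/semg evaluate --ckpt model.rds --data data
```

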