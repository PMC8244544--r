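# stomatrack

Automatic analysis of stomatal dynamics from time-lapse microscope video of
leaf surfaces. Stomatal behaviour is often *patchy* — neighbouring stomata on
the same leaf open and close differently — and studying it requires following
each individual stoma through a video rather than scoring static snapshots.
`stomatrack` implements the full analysis chain:

- **Tracking.** One kernelized correlation filter (KCF) per selected stoma:
  ridge regression over all cyclic shifts of a padded, cosine-windowed
  grayscale template, solved in the frequency domain with a Gaussian kernel
  (training $\hat\alpha = \hat y/(\hat k^{xx}+\lambda)$, detection by the
  argmax of $\mathcal{F}^{-1}(\hat k^{xz}\odot\hat\alpha)$). Stomata are
  stationary, so this classical tracker needs no training data.
- **Segmentation.** A UNet-style encoder–decoder with a depthwise-separable
  (MobileNet-style) encoder and four squeeze-and-excitation channel-attention
  blocks on the skip features f1–f4, softmax head, per-pixel cross-entropy,
  Adam (lr 0.001, batch 5), He initialization. Implemented from scratch
  (C++ convolution kernels, reverse-mode tape in R) and validated against
  finite differences and brute-force convolution oracles.
- **Quantification.** Per-stoma stomatal opening area (SOA = aperture pixel
  count) time series, smoothed first-derivative closure-rate curves,
  cross-stoma summaries, and Pearson correlations of mean SOA with
  gas-exchange parameters (Pn, Ci, Gs, Tr).
- **Synthetic scenes.** A ground-truthed generator renders microscope-like
  videos of stomata with programmed closure kinetics (constant, linear,
  logistic), so every stage is testable without real recordings.
- **Evaluation.** PA / CPA / MPA / IoU / MIoU from pooled confusion counts,
  plus the published reference metrics of the augmentation × SE-block
  ablation for consistency checks.

## Worked example

Simulate a 10-minute chilling-stress closure scene (three stomata closing at
staggered rates), train a small aperture segmenter on synthetic crops, and
run the pipeline:

```r
library(stomatrack)

sc <- scene_chilling_demo()            # 192x144 px, 0.1 fps, 600 s
gen <- generate_video(sc, "demo", write_masks = FALSE)
head(gen$table, 3)
#>   frame_index time_s stoma_id soa_analytic_px2 soa_raster_px
#> 1           0      0        1         307.8552           303
#> 2           0      0        2         307.8676           309
#> 3           0      0        3         307.8381           307

crops <- synth_crop_dataset(20, size = 64, seed = 7)
cfg <- seg_config(input_size = c(64, 64), width_multiplier = 0.25,
                  epochs = 12, seed = 1)
model <- train_segnet(seg_model_new(cfg), crops)

res <- run_pipeline(list(video = "demo/frames", model = model,
                         boxes = list("13,8,64,64", "98,18,64,64",
                                      "53,73,64,64"),
                         interval = 1, out_dir = "out"))
head(res$soa, 3)
#>     time_s stoma_id soa_px flagged
#> 1        0        1    401   FALSE
#> 61       0        2    482   FALSE
#> 121      0        3    362   FALSE

sapply(res$rates, min_rate_time)       # time of fastest closure per stoma
#> [1] 120 220 300
```

The three stomata were programmed with logistic-closure midpoints 120, 210
and 300 s; the recovered fastest-closure times (120, 220, 300 s, on a 10-s
sampling grid) rank them correctly — the faster closers close earlier, the
patchy-closure signature the pipeline is built to measure. `out/soa.csv` and
`out/rate.csv` hold the full tables. Held-out segmentation quality of this
quickly trained demo model:

```r
held <- synth_crop_dataset(5, size = 64, seed = 99)
aggregate_metrics(lapply(held, function(p)
  list(truth = p$mask, pred = predict_mask(model, p$image))))
#> PA 0.9827  MPA 0.9604  MIoU 0.9198  (n = 20480 px)
#>   CPA: 0.9892 0.9316
#>   IoU: 0.9806 0.8591
```

For production-quality synthetic training, `train_synthetic_segnet()` is the
package's reference recipe (150 crops, supervised at a 2× upsampled 128×128
input so the aperture boundary is localized below native pixel pitch — the
accuracy small, closing apertures need; see the methods vignette).

A command-line front-end with `run | simulate | train | evaluate | track |
analyze` subcommands is installed at `inst/cli/stomatrack.R`, driven by a
YAML config (see `?read_run_config`).

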