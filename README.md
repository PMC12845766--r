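# maunet

Binary semantic segmentation of cell nuclei in microscopy images, built
around two ideas:

1. **Balance-aware patch extraction.** Microscopy datasets are dominated by
   background pixels. Each image of height *h* and width *w* is covered by
   `k x k` sliding windows with stride `s` (`ph = ceil((h-k)/s) + 1` rows,
   `pl = ceil((w-k)/s) + 1` columns, `N = ph * pl` patches); a patch
   survives only if its foreground pixel count strictly exceeds a threshold
   (default 9), leaving `N_alpha = N - alpha` patches per image, where
   `alpha` counts the discarded, class-imbalanced ones. A random fraction
   of the surviving training patches receives flips / 90-degree rotations /
   Gaussian blur.
2. **A lightweight asymmetric U-Net.** A six-level encoder-decoder with
   skip connections on 128x128x3 inputs whose channel schedule narrows in
   the deep encoder (the second convolutions of downblocks 5 and 6 drop to
   16 and 32 channels; bottleneck 2x2x512 -> 2x2x64), ending in a 1x1
   convolution to 2 softmax channels. Training uses Adam with decoupled
   weight decay, binary cross-entropy, a stepwise learning-rate schedule
   (`lr = lr0 * 0.5^floor(epoch / (epochs/8))`), early stopping, and
   best-checkpoint selection by validation F1/MeanIoU.

Evaluation reports precision, recall, F1 and MeanIoU (mean of foreground
and background intersection-over-union) from pooled pixel confusion
counts. A seeded synthetic microscopy generator (clustered elliptical
nuclei on textured noisy backgrounds, written in the standard
`<id>/images/`, `<id>/masks/` instance-mask folder layout) makes the whole
pipeline runnable and testable without any external download.

The convolutional engine — forward pass and backpropagation — is
implemented inside the package (im2col + BLAS via RcppArmadillo) and is
verified against finite differences in the test suite.

## Worked example

```r
library(maunet)

# 32 synthetic microscopy images, ~5% foreground, heterogeneous sizes
records <- generate_dataset(32, cfg_template =
                              synth_config(target_fg_fraction = 0.05,
                                           seed = 42))
split <- split_dataset(records, seed = 42)
print(split)
#> <dataset_split: 25 train / 3 validation / 4 test (seed 42)>

patches <- prepare_patch_dataset(split,
             ada_params(k = 128, s = 64, alpha_threshold = 9,
                        aug_fraction = 0.25, seed = 42))
print(patches)
#> <patch_dataset: 316 train / 32 validation / 36 test patches (k=128, s=64, alpha>9)>

head(patches$report[, c("id", "N", "alpha", "N_alpha",
                        "fg_fraction_before", "fg_fraction_after")], 3)
#>          id  N alpha N_alpha fg_fraction_before fg_fraction_after
#> 1 synth-017 12     0      12         0.04179891        0.04179891
#> 2 synth-005 12     0      12         0.05682882        0.05682882
#> 3 synth-001  9     1       8         0.03841824        0.04318237
```

`N` patches were extracted per image, `alpha` of them were discarded for
having at most 9 foreground pixels, and the foreground fraction of the
surviving ensemble (`fg_fraction_after`) is correspondingly higher than
before filtering — the class-rebalancing effect the extraction stage
exists for.

```r
# a width-reduced model, short-budget settings (see the methods vignette)
fit <- maunet(patches$train, patches$validation,
              spec = maunet_spec(width_scale = 0.25),
              config = train_config(lr0 = 1e-3, batch_size = 8,
                                    epochs = 40, interval_fraction = 1,
                                    patience = 50, seed = 42))
print(fit)
#> Asymmetric U-Net nucleus segmentation model
#>   118,386 trainable parameters (width scale 0.25)
#>   trained 40 epoch(s), best epoch 39
#>   best validation: F1 0.9758, MeanIoU 0.9749

plot(fit)                      # loss / F1 / MeanIoU curves, lr steps
evaluate_network(fit, patches$test)
#> MeanIoU 0.9789 | Precision 0.9738 | Recall 0.9862 | F1 0.9800
#>   IoU(fg) 0.9607  IoU(bg) 0.9970  Accuracy 0.9972
```

The run takes a few minutes on one CPU. The four headline numbers are the
pooled test-patch MeanIoU, precision, recall and F1; `IoU(fg)` is the
nucleus-class intersection-over-union that MeanIoU averages with the
background class. The full-width architecture is `maunet_spec()`;
`shape_trace(maunet_spec())` prints its layer table, and
`build_network()` / `count_parameters()` instantiate and size it
(1,886,178 parameters at full width).

`run_pipeline(run_config(out_dir = "runs/exp1"))` orchestrates
synthesize -> split -> extract -> train -> evaluate end to end and writes
`balance_report.csv`, `history.csv`, `best_weights.rds`, `report.json` to
the output directory. A thin CLI over the same functions ships in
`inst/scripts/maunet` (subcommands `synth`, `prepare`, `train`, `eval`,
`run`).

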