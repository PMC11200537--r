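# mscaseg

Volumetric brain tissue segmentation with 3D multiscale convolutional
attention and edge-overlap label-quality weighting, implemented end to end
in R (with compiled kernels) and exercised on synthetic brain phantoms.

The package segments skull-stripped T1-weighted volumes into background,
cerebrospinal fluid (CSF), gray matter (GM) and white matter (WM). Three
ideas are implemented in full:

1. **A five-stage 3D encoder–decoder with multiscale convolutional
   attention (MSCA).** Each attention block aggregates features with a
   depth-wise 5³ convolution, runs them through parallel chains of
   depth-wise *strip* convolutions (k×1×1, 1×k×1, 1×1×k for k = 5, 7, 11 —
   the receptive field of a dense k³ kernel at a fraction of the
   parameters), mixes channels with a 1×1×1 convolution, and multiplies the
   result element-wise with the block input. Deep supervision attaches a
   segmentation head to every decoder resolution.
2. **A compound, quality-weighted loss.** Deep-supervised soft Dice plus
   cross-entropy, and a data-quality term that multiplies the
   cross-entropy of each training patch by W_Data — the Dice overlap
   between the Canny edge map of the intensity patch and that of its label
   patch. Patches whose annotations disagree with the image edges
   contribute proportionally less gradient, making training robust to
   label noise.
3. **Faithful training and evaluation machinery.** Patch-based SGD
   (momentum 0.99, weight decay 3e-5, poly learning-rate decay from 0.01),
   class-balanced foreground-biased patch sampling, flip/rotation
   augmentation, Gaussian-weighted sliding-window inference, per-class
   Dice and 95th-percentile Hausdorff distance (exact distance transform),
   and paired t-tests with Bonferroni correction.

Since real MRI cohorts cannot ship with a package, `generate_phantom()`
synthesises supervision: nested ellipsoidal tissue shells with realistic
mean intensities, a smooth multiplicative bias field and Rician noise,
plus `corrupt_labels()` for controlled annotation errors (erosion,
dilation, boundary jitter, class swaps). The phantoms are fixtures for
exercising and testing the machinery, not a benchmark; absolute scores on
them do not transfer to real brains.

Everything — convolutions, transposed convolutions, depth-wise strip
convolutions, instance normalization, the full backward pass — is
implemented in this package (R + Rcpp); there is no deep-learning
framework underneath. Problem sizes in the examples and tests are chosen
so that every step runs in minutes on a single CPU.

## Worked example

Train the tiny preset on one 96³ phantom and evaluate it:

```r
library(mscaseg)

ph  <- generate_phantom(phantom_config(), seed = 11)
cfg <- train_config(max_epoch = 20L, iters_per_epoch = 10L,
                    patch_size = 32L, batch_size = 2L, seed = 1L)
fit  <- train_model(list(list(volume = ph$volume, labels = ph$labels)),
                    cfg, arch_config_tiny())
pred <- predict_volume(fit$net, ph$volume, cfg)
evaluate_segmentation(pred, ph$labels, spacing = ph$volume$spacing)
```

On this machine (one CPU core, ~3.5 minutes of training) this prints:

```
  class dice_pct   hd95_mm
1   csf 19.06052 20.346990
2    gm 44.41731 36.249138
3    wm 56.29318  9.949874
4 macro 39.92367 22.182001
```

200 iterations is a smoke-test budget: the same pipeline run for 600
iterations reaches a mean foreground Dice of about 0.89 on its training
phantom. Label-quality scoring is a one-liner:

```r
ph  <- generate_phantom(phantom_config(), seed = 11)
bad <- corrupt_labels(ph$labels, corruption_spec("erode", 2), seed = 1)
mean(qc_score_volume(ph$volume, ph$labels, 32L)$w_data)  # 0.4178
mean(qc_score_volume(ph$volume, bad,       32L)$w_data)  # 0.0093
```

The eroded annotation scores visibly lower — exactly the signal the
data-quality loss exploits.

A command-line interface with `phantom`, `describe`, `qc-score`, `train`,
`predict` and `evaluate` subcommands is installed under
`inst/cli/mscaseg`; see the header of that script for usage.

## Package layout

- `R/volume_io.R` — NIfTI I/O, one-hot encoding, patch sampling
- `R/phantom.R` — phantom generation, bias field, label corruption
- `R/layers.R`, `src/` — conv/deconv/depth-wise/instance-norm kernels, forward and backward
- `R/msca.R` — the multiscale convolutional attention block
- `R/network.R` — architecture assembly, forward pass, summaries
- `R/quality_edges.R` — Canny edges, W_Data quality weights
- `R/losses.R` — Dice, cross-entropy, deep supervision, quality-weighted total loss
- `R/metrics.R` — Dice, HD95, per-class reports, paired tests
- `R/train.R` — SGD loop, schedules, augmentation, sliding-window inference
- `inst/cli/mscaseg` — command-line interface
- `vignettes/methods.Rmd` — methods description
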