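# pestseg

Semantic segmentation of insect pests in field-crop imagery with a
multiscale **vision-Mamba U-Net**, implemented natively in R.

Field pest segmentation is dominated by three difficulties: the insects
are small (often tens of pixels, with one-pixel-wide legs and antennae),
they appear at several scales in one frame, and they blend into textured
vegetation, so pest pixels are a heavily outnumbered minority class. This
package provides, as tested library code:

* the 2D **selective-scan** machinery (SS2D): a feature map is flattened
  along four traversal directions, each sequence is run through the
  input-dependent state-space recurrence
  `h_t = exp(δ_t A) h_{t−1} + δ_t B_t x_t`, `y_t = C_t·h_t + D x_t`
  (with `A = −exp(A_log)` so the transition stays in (0, 1]), and the
  scanned sequences are folded back and summed;
* the composite blocks built on it — visual state-space (VSS) blocks,
  multiscale VSS encoder blocks (parallel 1/3/5-kernel convolution set),
  a dilated-convolution attention bottleneck (rates 1/3/5, CBAM-style
  spatial gate), and channel-aware attentional skip connections;
* the symmetric encoder–decoder with 4×4 patch embedding, patch
  merging/expanding, and the stage ladder
  `H/4×W/4×C → … → H/32×W/32×8C` and back (`C = 96` by default);
* the hybrid loss `0.4·CE + 0.6·Dice` (smoothing 0.001), confusion-matrix
  pixel accuracy (PA) and mean IoU, and an SGD training loop (batch 24,
  lr 0.001, momentum 0.9, weight decay 1e-4, validation every 200 of
  3,000 iterations) that checkpoints only on best validation MIoU;
* a synthetic pest-scene generator (elliptical bodies, thin polyline
  appendages, textured low-contrast backgrounds, class imbalance), the
  full augmentation suite (crop / flips / rotate / shift / photometric
  jitter / Mixup / CutMix) and seeded 6:2:2 dataset splitting — so the
  entire pipeline runs and is tested with no external data.

Everything — including reverse-mode autodiff — is implemented in base R
plus a small C++ kernel for the scan recurrence; gradients are verified
against finite differences and the recurrence against a brute-force
unrolled oracle.

## A worked example

```r
library(pestseg)

# one synthetic 64x64 field scene
sc <- generate_scene(scene_spec(64, 64, seed = 7))
sum(sc$mask)                    # 221 pest pixels of 4096 (5.4% cover)

# a reduced model (C = 16, one block per stage, N = 4)
cfg <- model_config(base_channels = 16, enc_depths = c(1, 1, 1, 1),
                    dec_depths = c(1, 1, 1, 1), state_size = 4)
model <- build_model(cfg, seed = 1)
model$n_params                  # 1051333 learnable parameters

logits <- model_forward(model, sc$image)   # 64 x 64 x 2 per-pixel logits
pred   <- predict_mask(model, sc$image)    # integer mask, argmax of softmax

cm <- update_confusion(confusion_matrix(2), pred, sc$mask)
pixel_accuracy(cm)              # 0.5107  (untrained: near chance)
mean_iou(cm)                    # 0.2750

hybrid_loss(logits, sc$mask, loss_config())  # 0.5785
```

An untrained network scores near chance; `train_model()` runs the SGD
protocol and returns the best-validation checkpoint plus the metric
history:

```r
scenes <- lapply(1:8, function(i) generate_scene(scene_spec(64, 64, seed = i)))
fit <- train_model(model, scenes, scenes,
                   train_config(iterations = 300, batch_size = 4,
                                eval_period = 100))
fit$history                     # iteration, loss, val PA, val MIoU
evaluate_model(fit$model, scenes)
```

A command-line interface over the same functions lives in
`inst/cli/pestseg.R` (`synthesize`, `train`, `evaluate` subcommands).
The methods vignette (`vignettes/pest-segmentation-methods.Rmd`) documents
the model, its numerical choices, the generator's scope and the package's
known limitations.

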