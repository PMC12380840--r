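Package: pestseg
Title: Multiscale Vision-Mamba U-Net for Crop Pest Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of small insect pests in field-crop
    imagery with a multiscale vision-Mamba U-Net. Provides the 2D
    selective-scan state-space machinery (directional scan expansion, the
    selective S6 recurrence, scan merging), multiscale visual state-space
    encoder blocks, a dilated-convolution attention bottleneck,
    channel-aware attentional skip connections, patch merging/expanding,
    a hybrid Dice plus cross-entropy loss, pixel-accuracy and mean-IoU
    evaluation, SGD training with checkpoint-on-best-validation, and a
    synthetic pest-scene generator with the full augmentation suite
    (flips, crops, rotation, shifts, photometric jitter, Mixup, CutMix)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
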