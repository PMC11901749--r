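Package: phytofuse
Title: Multimodal Image-Sensor Fusion for Plant Disease Detection
Version: 0.1.0
Authors@R: person("phytofuse", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale framework for detecting foliar diseases from paired
    leaf images and environmental sensor windows. Provides a controllable
    synthetic multimodal dataset generator with planted class ambiguities,
    lesion-aware data augmentation (CutMix, Mosaic, GridMask), small
    convolutional and transformer-style encoders implemented in base R,
    weighted multimodal fusion with a joint embedding attention mechanism,
    a composite embedding loss (cross-entropy plus cosine alignment),
    detection evaluation (per-class AP and mAP at an IoU threshold),
    a seeded training and ablation harness, and post-training magnitude
    pruning and uniform quantization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    digest,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
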