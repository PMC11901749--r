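---
title: "Multimodal fusion for plant disease detection: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fusion for plant disease detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phytofuse)
```

## The problem

Foliar diseases of greenhouse crops (the running example is eggplant, with
five classes: brown spot, brown stripe, fusarium wilt, leaf mold and bacterial
leaf spot) are diagnosed in the field from two complementary information
sources: what the lesion *looks like*, and what the *environment* has been
doing — several of these diseases are strongly humidity-linked. phytofuse is a
desk-scale, fully inspectable implementation of a detection pipeline that
fuses leaf images with hourly environmental sensor windows (temperature,
humidity, light, CO2), so that every claim about the benefit of fusion,
attention, or the composite loss can be tested end-to-end on synthetic data
with known ground truth.

## The model

The assembled classifier/detector is:

1. **Image encoder** (`encode_image`): a three-block stride-2 CNN ("tinycnn",
   channels 3→8→16→32), giving an 8×8×32 feature map for a 64×64 input. Each
   spatial position is projected to the shared dimension D = 32 and
   layer-normalized, yielding 64 image tokens. A ResNet-50 backbone is part of
   the interface but deliberately not runnable offline: it would require
   downloading pretrained weights, and nothing in the acceptance properties
   may depend on an external artifact.
2. **Sensor encoder** (`encode_sensors`): each channel's hourly stream is
   averaged into 6 equal time bins, standardized with statistics computed on
   the *training split only* and frozen, embedded as one token per
   (channel, bin) with channel and bin positional encodings, and passed
   through 2 single-head self-attention encoder layers (residual + layer
   normalization). This is a from-scratch transformer-style encoder: the
   input is numeric telemetry, not text, so no pretrained language model is
   involved or appropriate.
3. **Fusion** (`fuse`): the trained pipeline scales image tokens by a learned
   α (a sigmoid of one unconstrained scalar, initialized at 0.5) and sensor
   tokens by 1−α, then concatenates the token sets. The vector-level variants
   — weighted sum `αFv + (1−α)Ft`, plain concatenation, and bilinear
   attention pooling `softmax(FvᵀWFt)·Fv` — are exposed for the ablation
   harness. "Weighted concatenation" has no unique published formula; scaling
   each block by its weight before concatenating honors both the term and the
   weighted-sum algebra, and reduces to plain concat (up to a factor 0.5 per
   block) at α = 0.5.
4. **Embedding attention** (`embedding_attention`): a stack of 2 scaled
   dot-product self-attention layers (Q = WqF, K = WkF, V = WvF;
   softmax(QKᵀ/√d)·V added residually, then layer-normalized) applied
   *jointly* over the concatenated image + sensor tokens. That joint span is
   the entire point: the ablation arm `attention_kind = "self"` runs the same
   stack over image tokens only, and `"cbam"` applies channel-then-spatial
   gating to the convolutional map instead.
5. **Head**: tokens are mean-pooled, layer-normalized, passed through one
   fully connected ReLU layer (`Fm′ = ReLU(Wf·Fm + bf)`), then two linear
   maps: 5 class logits and a 4-vector single-box regressor in normalized
   coordinates.

**Loss.** The training objective is the configured classification loss plus a
smooth-L1 box term (weight `lambda_box = 1`):

* `"ce"`: class-weighted cross-entropy with soft-label support (CutMix and
  Mosaic produce mixed labels);
* `"focal"`: the batch-mean multi-class focal form
  `−α(1−ŷ)^γ·y·log ŷ` (γ = 2, α = 1 by default), which reduces exactly to CE
  at γ = 0, α = 1;
* `"embedding"` (default): cross-entropy plus `lambda_align = 0.5` times the
  cosine alignment loss `1 − cos(fv, ft)` between the per-sample pooled image
  and sensor projections. Alignment is computed on *pre-fusion* pooled
  projections — the only reading under which both feature vectors still exist
  as separate objects — and is active only when both modalities are present.

All gradients are hand-derived and verified against central finite
differences in the test suite (tolerance 1e-4 relative).

## The synthetic world

No public dataset exists for this pipeline, so the generator
(`generate_dataset`) is a first-class module. It renders parametric lesions
(sharp-bordered ellipses, elongated streaks, white patches, yellow-gray
patches, wet blurred halos — one style per class) on noisy green leaf-like
backgrounds, and draws each sample's sensor window from a class-conditional
regime (leaf mold and fusarium wilt from high-humidity regimes, matching the
field knowledge that these fungal diseases accompany humid conditions).

The key design property is the **planted ambiguity** controlled by
`confusability` (c):

* a fraction c of brown spot and bacterial leaf spot images are rendered with
  one shared "ambiguous spot" appearance — only humidity separates them;
* the same fraction of leaf mold and fusarium wilt samples draw their sensor
  window from one shared regime — only lesion appearance separates them.

Hence any image-only classifier is bounded by `1 − c/5` accuracy, any
sensor-only classifier by the same bound, while the joint Bayes accuracy
stays at ~1. The generator ships its own Bayes rule (`bayes_predict`), which
reads the planted latents and coin-flips the irreducible pairs; the test
suite verifies the realized accuracy sits within 3 standard errors of the
closed form.

Numeric defaults chosen once, with reasoning:

* image size 64×64 — the smallest size giving the CNN three stride-2 stages;
* sensor window 24 h at one reading per hour — one day of context; the
  source protocol never states the window, so it is configurable and the
  default is flagged as a guess;
* per-window regime offsets (SDs 1.5 °C, 3 %RH, 60 a.u., 30 ppm) and smaller
  within-window jitter, plus a diurnal sinusoid on temperature and light —
  class regimes are separated by ≥ 3 between-window SDs on at least one
  channel so that the *unambiguous* structure is learnable at desk scale;
* sensor readings are quantized to 3 decimals (instrument resolution), which
  also makes CSV round-trips exact;
* one lesion (and box) per image by default, keeping the single-box
  regression head honest; multi-lesion rendering is available.

What the generator does **not** emulate: photorealistic leaf texture, sensor
hardware error models (the ±0.5 °C accuracy of the usual DHT22 probe is
documented, not simulated), weather dynamics beyond the stationary per-window
draw, and correlated multi-disease infections. A green test therefore
establishes that the *pipeline machinery* behaves as specified and that the
fusion advantage emerges when the information structure demands it — not that
any particular field accuracy would be achieved.

## Augmentation semantics

* `cutmix` implements both readings of the published rule: `"region"`
  (default) replaces a rectangle and sets λ to the realized retained-pixel
  fraction; `"blend"` is the literal pixel-wise convex combination with
  λ ~ Beta(β, β), β = 1 by default (no value is published). With
  `preserve_lesions = TRUE` the paste is placed (≤100 attempts) so it neither
  covers a lesion of the base image nor truncates the pasted lesion; an
  infeasible geometry falls back to the identity mix with a warning.
* `mosaic` tiles four images at a split point, remaps and clips boxes
  (dropping remnants below 20 % of their scaled area), and mixes labels by
  quadrant area — the source describes no label rule, and area weighting is
  consistent with CutMix's area semantics. Resizing is nearest-neighbor so a
  pixel-conservation property can be asserted exactly.
* `gridmask` zeroes a periodic grid of square blocks (`unit` period, kept
  fraction `ratio`, random phase); lesion boxes are exempted after grid
  generation. Random mode samples `unit` from [min_side/8, min_side/4] and
  `ratio` from [0.3, 0.6].

Sensor windows pass through augmentation unchanged — whether the source
augmented telemetry is unstated, and inventing a scheme would change the
information structure the acceptance properties rely on.

## Optimization protocol

Adam (lr 0.001, cosine-annealed per epoch, weight decay 1e-4, batch 32),
stratified 70/15/15 holdout by default with 5-fold CV available, 15 epochs at
desk scale, all RNG derived from one master seed through named substreams
(data / split / init / trainloop), single-threaded and bit-reproducible.
Class weights (`inverse_frequency`) and sensor standardization are computed
on the training portion only; a test asserts that recomputing them with
validation data included yields different values, proving no leakage.

Two conditioning choices mattered empirically and are deliberate deviations
from a bare reading of the architecture: layer normalization of the projected
image tokens (so both modalities enter fusion on the same scale) and a final
layer normalization of the pooled fused vector before the FC head (mean
pooling over ~64–88 unit-scale tokens otherwise shrinks the feature scale by
~1/√N and starves the head of gradient within the 15-epoch budget). Both are
standard transformer practice.

The box head is an artifact addition: the evaluation protocol reports mAP@75,
but no localization mechanism is published; a single-box smooth-L1 regressor
is the smallest head that makes the AP machinery exercisable end-to-end. Its
desk-scale mAP@75 is expectedly poor (a global-feature regressor rarely
reaches IoU 0.75) and no acceptance property depends on it.

## Metrics

Classification metrics come from the 5×5 confusion matrix (one-vs-rest
precision/recall, trace accuracy, macro averages; 0/0 is defined as 0 with a
logged note). Detection AP uses greedy score-ordered matching (ties by higher
IoU, then lexicographic image id) at IoU ≥ 0.75 on half-open boxes, and
all-point interpolation of the precision-recall curve (the published
continuous integral; 11-point variants were considered and rejected as a
larger departure from the integral). Classes without ground truths are
excluded from mAP rather than scored zero. Both AP and mAP are verified
exactly against a brute-force prefix-enumeration oracle on 200 random
instances.

## Compression

`prune_weights` keeps a weight iff |w| strictly exceeds ε (the published rule
says "exceeds"; equality prunes), and is exactly idempotent.
`quantize_weights` uses round-half-to-even (R's `round`; the rounding mode is
unpublished) with the reconstruction bound |w − ŵ| ≤ Δ/2 asserted
exhaustively. Activation quantization is out of scope: it would need
calibration passes that are nowhere specified.

## Known limitations

* The 15-epoch, 90–165-step optimization budget leaves all models somewhat
  short of their information ceilings; the acceptance properties are
  formulated as orderings and margins, not absolute accuracies, for exactly
  this reason.
* Single-box localization cannot express multi-lesion images (off by
  default in the generator).
* `fuse(mode = "bilinear")`'s softmax axis is chosen as the image-token axis,
  the only shape-consistent reading; this is flagged rather than settled.
* The O(n²·d) cost of joint attention is accepted at desk scale; sparse or
  factorized attention is documented as the known mitigation and deliberately
  not implemented.
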