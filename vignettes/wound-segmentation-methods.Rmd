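---
title: "Dual-attention wound segmentation: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-attention wound segmentation: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

woundseg builds, trains and compares encoder–decoder convolutional networks
for binary wound segmentation of RGB photographs. This vignette is the
package's account of the science it implements: the model family, the loss
and metric conventions, the training protocol, the synthetic scene generator
that makes everything testable offline, and the design decisions taken where
the architecture family leaves choices open.

## The segmentation problem

Chronic and acute wounds (diabetic foot ulcers, pressure ulcers, burns,
surgical wounds) are photographed in clinical settings and must be delineated
from the surrounding skin before any downstream measurement — area, healing
rate, tissue composition — is possible. The task is pixelwise binary
classification: each pixel of a 640 × 480 photograph is wound or background.
Two properties make it hard: extreme class imbalance (wound pixels range from
0 to roughly a third of the frame; many images contain no wound at all) and
photographic nuisance structure (shadows, specular reflections, debris, and
skin tones spanning the whole Fitzpatrick scale).

## Model family

All five variants share one encoder–decoder skeleton with four 2× poolings
(inputs therefore must be multiples of 16) and a decoder that restores full
resolution with 2 × 2 transposed convolutions, concatenating the
same-resolution encoder features at each level (skip connections).

* `unet` — the classic double-convolution U-Net: encoder widths
  64, 128, 256, 512 with a 1024-wide bridge; no batch-norm; the head is a
  3 × 3 convolution to two channels followed by a 1 × 1 convolution.
* `vgg16_unet` — the VGG16 convolutional stack
  (64,64 | 128,128 | 256,256,256 | 512,512,512 | 512,512,512) as encoder,
  skips taken before each of the first four poolings, block 5 acting as the
  bridge; decoder widths 512, 256, 128, 64 with two 3 × 3 convolutions per
  level, each followed by batch normalisation; 1 × 1 two-channel head.
* `se_vgg16_unet` — adds a squeeze-and-excitation (SE) block after every
  encoder block and every decoder level (nine sites).
* `ag_vgg16_unet` — adds an additive attention gate (AG) on each of the four
  skip connections.
* `se_ag_vgg16_unet` — the dual-attention model: both mechanisms together.

Every variant ends in a two-channel softmax; the package reports the
foreground channel as a single probability map in (0, 1), and
`predict_mask()` binarises it at a strict `> 0.5`.

**Squeeze-and-excitation.** For a feature map with C channels, global average
pooling produces one descriptor per channel ("squeeze"); two bias-free fully
connected layers — C → C/r with ReLU, then C/r → C with sigmoid
("excitation") — produce per-channel scales in (0, 1) that multiply the map.
The reduction ratio defaults to r = 64.

**Attention gate.** The skip features x (F_l channels) are projected to F_int
channels by a 1 × 1 stride-2 convolution so they land on the coarser grid of
the gating signal g — the decoder state just before the level's
up-convolution (the bridge for the first level). g is projected by a 1 × 1
convolution, the sum passes through ReLU, a 1 × 1 projection to one channel
and a sigmoid, giving attention coefficients α ∈ (0, 1) at the coarse grid;
α is upsampled (nearest neighbour) back to the skip grid and multiplies x
across all channels. F_int defaults to F_g/4, giving (128, 128, 64, 32)
across the four levels.

### Calibration of the unstated hyperparameters

The family's reference parameter totals are exact integers —
31,032,840 (U-Net), 25,862,402 (VGG16 U-Net), 25,892,354 (+SE),
26,123,558 (+AG), 26,153,510 (dual) — and several block hyperparameters
(biases, batch-norm placement, F_int, the output head) are not stated
anywhere. The package therefore fixed them by a documented discrete search
over the plausible design space, keeping only configurations whose counts
reproduce the reference totals exactly:

* The SE delta (+29,952) is matched exactly by bias-free excitation layers
  with r = 64 over the nine insertion sites (Σ 2C²/64).
* The AG delta (+261,156) has a *unique* solution in the searched space:
  gating from the pre-upsampling decoder state, biased 1 × 1 projections, no
  batch-norm in the gate, and F_int = F_g/4. All alternatives (gating from
  the upsampled state, 2 × 2 stride-2 skip projections, bias-free variants,
  batch-normalised ψ, constant or F_l-proportional F_int) miss the total.
* The VGG16 U-Net decoder total is reproduced only with two biased 3 × 3
  convolutions per level, each followed by batch normalisation, and a
  two-channel 1 × 1 head. Counts include the batch-norm moving statistics
  (4C per layer) — the convention of framework model summaries. A
  single-channel sigmoid head misses the total by 65; the two-channel softmax
  is therefore taken as the family's actual head, and the package folds it
  back into a single foreground map at the interface.
* The U-Net total is reproduced by the classic biased double-convolution
  stack without batch-norm and the widely copied two-stage head
  (3 × 3 → 2 channels with ReLU, then 1 × 1 → 2 channels).

These choices are frozen in `build_network()`; `count_params()` and the
acceptance script verify the five totals and the additivity of the two
attention deltas (29,952 + 261,156 = 291,108).

## Loss, metrics and class weights

Training minimises class-weighted cross-entropy over pixels,

$$L = -\frac{1}{N}\sum_i \big[ w_+ t_i \log p_i + w_- (1-t_i)\log(1-p_i) \big],$$

with probabilities clipped to [1e-7, 1 − 1e-7]. Equal weights recover plain
binary cross-entropy (asserted to 1e-12 in the tests).
`derive_class_weights()` computes inverse-frequency weights from the training
masks, normalised so w₊ + w₋ = 2 (a corpus with wound fraction f gives
w₊ = 2(1−f), w₋ = 2f); the ratio is capped (default 100) so an all-background
corpus cannot produce an infinite weight. The exact weighting rule is a
package choice — only the use of a weighted cross-entropy is given — and the
cap interacts with the normalisation: the cap binds the *ratio*, keeping the
sum-2 normalisation, rather than assigning the raw cap as a weight.

Evaluation uses the Dice coefficient 2|P∩T|/(|P|+|T|) and IoU |P∩T|/|P∪T| on
binarised predictions, related by IoU = Dice/(2 − Dice). Two empty masks
score 1.0: the corpus deliberately contains wound-free images, and a correct
all-negative prediction should be rewarded, not treated as undefined. Scores
are computed per image and then averaged (mean ± population standard
deviation), never pooled over the corpus.

## Training protocol

`train()` runs Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) at learning rate 1e-5
with batch size 2 by default, iterating seeded shuffled mini-batches. After
each epoch the validation loss is computed; training stops when it has not
strictly decreased by at least 1e-8 for `patience = 10` consecutive epochs,
and the weights of the best-validation epoch are restored. The improvement
tolerance and the restoration step are package choices (only the stop
criterion is given); restoration is adopted because without it the returned
model is whatever the last — by construction non-improving — epoch produced.
Batch-norm layers use batch statistics during training (momentum 0.99,
ε = 1e-3 for the moving averages) and moving statistics at inference.

`fine_tune()` re-enters the identical loop from the incoming weights with a
fresh optimiser state and all layers trainable at the same learning rate —
layer freezing is deliberately not used, keeping the adaptation protocol
identical to initial training.

`split_by_patient()` guards against leakage: patients, not images, are
shuffled and apportioned 70/20/10 by largest-remainder rounding, so all
images of a patient travel together. "Balanced wound pixel distribution"
across subsets is implemented as a post-hoc report (`split_balance()`), not
an optimisation — no balancing algorithm is specified, and silently
optimising the split would interact badly with the leakage guarantee.

## Statistical comparison

`compare_models()` takes per-image scores of several variants on the
identical image set and, for every variant pair and each metric, screens the
paired differences for normality (Shapiro–Wilk — the screen itself is named
nowhere, so the most common omnibus test was fixed) and applies a two-sided
paired t-test, t = mean(d)/(sd(d)/√n), df = n − 1, at a 99% significance
level (α = 0.01). Identical score columns raise an explicit degenerate-case
error rather than a silent p = 1. No multiple-comparison correction is
applied across the pairwise grid, matching the presentation style of
ablation tables in this literature; report footers state this.

## The synthetic scene generator

No wound photograph collection can ship with the package, so
`generate_scene()` builds statistically wound-like scenes that are a
deterministic function of (seed, index):

* background: one of six Fitzpatrick-scale-like skin tones with smooth
  low-frequency shading;
* 0–3 lesions per image (uniform; zero-wound images are a deliberate part of
  the corpus), each an ellipse of target area fraction 0.005–0.25 of the
  frame whose border is roughened by thresholded smooth noise — the support
  stays strictly inside the ellipse, so per-lesion area never exceeds the
  drawn fraction;
* lesion fill mixing granulation-red, slough-yellow and necrotic-dark tones
  with a darkened rim;
* optional artifacts — multiplicative shadow ramp, specular highlight,
  dark debris specks — each applied with probability 0.3; artifacts perturb
  the image only, never the mask;
* additive Gaussian pixel noise (σ = 3 on the 0–255 scale).

The defaults mirror the working resolution (480 × 640) and the imbalance
structure of clinical corpora (foreground fractions from 0 to ~50% in
aggregate). What the generator does *not* emulate: true wound texture and
specularity, camera optics, perspective and scale variation, anatomical
context (toes, heels, dressings), or annotation noise. Tests passing on
synthetic scenes therefore validate the machinery — shapes, gradients,
protocol semantics, determinism — not clinical segmentation quality.

## Numerical choices and problem sizes

* All computation is double precision on CPU; convolutions are im2col + BLAS
  GEMM processed in bands of output rows so buffers stay bounded at 640 × 480.
* Initialisation is Glorot-uniform under a fixed seed; building a network
  never perturbs the caller's RNG stream.
* Input scaling is pixel/255 with no mean subtraction.
* Binarisation uses a strict `> 0.5`; probability 0.5 exactly maps to
  background.
* Attention-map upsampling is nearest-neighbour: it preserves the (0, 1)
  range exactly and has an exact adjoint (2 × 2 block sum) for the backward
  pass.
* The test suite exercises blocks at 16–64 px and full end-to-end training at
  128 × 128 with 8 scenes — sizes chosen so the whole suite runs on one CPU
  core in minutes while still covering every code path at the full model
  width (the parameter counts are resolution independent). The end-to-end
  check trains the dual-attention variant to overfit its 8 training scenes
  (mean Dice > 0.9) over a fixed 40-epoch budget; it uses a larger learning
  rate (3e-4) than the clinical-protocol default, which is tuned for
  large-corpus generalisation rather than a small-sample capacity check.

## Known limitations

* The engine is a purpose-built CPU implementation: it trains the 26M
  parameter models at desk scale (small corpora, 128 × 128), not at
  clinical-corpus scale; no GPU path, no data augmentation.
* Pre-trained VGG16 encoder weights can be loaded through
  `load_pretrained_encoder()`, but the package does not ship or download
  them; all shipped results start from random initialisation.
* The synthetic scenes support protocol-level validation only; conclusions
  about real wound photographs require real data.
* Batch-norm statistics with batch size 2 are noisy; training curves
  oscillate more than framework users may expect at larger batch sizes.
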