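---
title: "Methods: an ensemble deep-learning classifier for bladder tissue images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an ensemble deep-learning classifier for bladder tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

White-light cystoscopy frames from transurethral resection of bladder tumour
(TURBT) procedures are classified into four tissue categories: high-grade
carcinoma (HGC), low-grade carcinoma (LGC), non-suspicious tissue (NST) and
no tumour lesion (NTL). Visual grading is hard — high- and low-grade lesions
can look alike — so the package combines three convolutional classifiers and
a voting rule rather than relying on a single network:

1. **CNN** — a small convolutional network (two 5×5 valid convolutions with
   8 and 16 filters, 2×2 max-pooling, a 400→120→84→K fully connected head,
   softmax output) on 32×32 inputs.
2. **GAN** — the same CNN architecture, trained on the train split augmented
   with images sampled from per-class generative adversarial networks.
3. **XDL** — an explainable VGG16-shaped backbone (13 3×3 convolutions in
   five pooled blocks, global average pooling, a linear head). Its Guided
   Grad-CAM saliency maps serve two purposes: post-hoc explanation, and
   attention-guided crop augmentation during training.

Before any training, the whole dataset passes an interquartile-range (IQR)
screen: a scalar feature per image (mean brightness by default), quartiles
Q1/Q3 over the dataset, and rejection outside
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`. This removes over- and under-exposed frames
that would otherwise pollute training.

Per test image the three members vote. With three members only three
agreement patterns exist, and the rule is exhaustive:

* **consensus** — all three agree: that class.
* **majority** — exactly two agree: their class.
* **accuracy fallback** — all disagree: the member with the highest stored
  validation accuracy decides (or, in `per_class` mode, the highest
  validation recall on its own predicted class — both readings of the rule
  appear in the literature, so both are implemented and selectable).

The *majority fault problem* — two weak members outvoting a strong
dissenter — is detected (dissenter accuracy strictly above both agreeing
members) and flagged in the outcome, but not overridden: the intended remedy
is assembling members with comparable accuracies, not a different rule.

## Saliency definitions

For feature maps \(A^k\) (spatial size \(W \times H\)) of a chosen
convolutional layer and the pre-softmax class score \(y^c\):

* Grad-CAM weight: \(w_k^c = \frac{1}{Z}\sum_i\sum_j
  \partial y^c / \partial A^k_{ij}\) with \(Z = W H\); the map is
  \(\mathrm{ReLU}(\sum_k w_k^c A^k)\), non-negative by construction.
* Guided backpropagation: the input gradient of \(y^c\) where every ReLU
  passes gradient only at positions with positive forward activation *and*
  positive incoming gradient; the final input gradient is clamped at zero
  and reduced to one channel by a per-pixel maximum over RGB.
* Guided Grad-CAM: the Grad-CAM map, bilinearly upsampled to input
  resolution, multiplied elementwise with the guided-backprop map. Its
  support is therefore contained in the upsampled Grad-CAM support.
* A per-class average of Guided Grad-CAM maps is available
  (`aggregate_guided_grad_cam()`) for visualization; the training pipeline
  uses the predicted-class map, which is the variant that localizes the
  decision actually taken.

Two conventions had to be pinned where the method description is ambiguous:
\(y^c\) is the **pre-softmax** score (standard CAM practice; the softmax
probability would only rescale gradients by \(p_c(1-p_c)\) and can underflow
for confident predictions), and the ReLU gate in guided backpropagation uses
**both** the forward and the gradient sign (the gradient-only half alone
would reduce to plain backpropagation with a clamp).

During XDL training, epoch 1 is a warm-up on unmodified images; from epoch 2
on, each epoch regenerates Guided Grad-CAM maps for the *current predicted
class* of every training image, crops each image to the bounding box of map
values ≥ 50% of the map maximum (4 px margin, clipped, resized back;
all-zero maps fall back to the uncropped image), and trains on originals
plus crops. "Repeat until the best feature weights are obtained" is read as
early stopping on validation accuracy with patience 3, returning the
best-validation weights.

## The neural-network engine

No deep-learning framework is a dependency: the package carries a small
reverse-mode engine (stride-1 convolutions via im2col/col2im in C++, 2×2
max-pooling, dense layers, global average pooling, nearest-neighbour
upsampling for the generator, ReLU/sigmoid/linear activations, minibatch SGD
with momentum). This is a deliberate design: Grad-CAM and guided
backpropagation need gradients with respect to *interior* activations and
modified backward rules, which the engine exposes directly. The backward
pass is verified against central-difference numerical gradients to 1e-7 in
the test suite.

Classifier inputs are centred (`pixel − 0.5`). A plain-SGD baseline at
learning rate 0.01 was evaluated first but provides too few updates at the
package's validation scale (10 epochs × ~10 minibatches) to leave chance
level; the package default is SGD with momentum 0.5
at learning rate 0.05 for the 32×32 branches (decayed by 0.9 per epoch for
the plain CNN and 0.8 per epoch for the augmented branch, which sees ~2.4×
more updates per epoch) and momentum 0.9 at a constant 0.015 for the deeper
XDL stack, with the global gradient norm clipped at 5 (the
13-layer stack occasionally produces an exploding minibatch that would
otherwise undo several epochs). Because validation accuracy oscillates at
this data scale, every branch returns the weights of its best-validation
epoch; the stored accuracy the vote consumes is recomputed from exactly
those weights. The XDL early stop (patience 3) is armed only after six
epochs — the deep stack sits at chance for the first few epochs, and
stopping on that noise would freeze an untrained checkpoint. Cross-entropy
on softmax outputs is the objective everywhere (forced by the softmax
output layer).

## GAN branch choices

* **One unconditional GAN per class.** The method must label generated
  images; per-class generators make the label sound by construction. A
  conditional GAN is out of scope.
* **Non-saturating generator loss** (ascend `log D(G(s))`): the minimax
  value `V(D,G) = E[log D(A)] + E[log(1 − D(G(s)))]` is the stated
  objective, but its raw generator gradient vanishes early; the
  non-saturating surrogate is the standard trainable form.
* Discriminator outputs are clamped to `[1e-7, 1 − 1e-7]` before logs, so
  the empirical value is always finite and ≤ 0; it equals `−2·log 2` exactly
  when D outputs 1/2 everywhere.
* Defaults: latent dimension 32 (standard normal), 2000 alternating steps,
  batch 16, synthetic images per class = size of the largest real class —
  all configurable; the stopping rule is simply the step budget.
* As a training diagnostic, the discriminator's real-vs-generated accuracy
  is recorded twice: once for a reference discriminator trained briefly
  against the frozen initial generator (near-perfect separation), and once
  at the end of adversarial training. Generator progress shows up as the
  final accuracy not exceeding the reference.

## Outlier screening choices

* Quartiles use sorted linear interpolation at position `p·(n−1)`
  (`stats::quantile` type 7) — pinned so fence values are exactly testable.
* The fence interval is **closed**: values exactly on a fence are kept.
  With a constant feature vector the fences collapse and nothing is
  rejected.
* Fences are computed over the whole dataset before splitting — one gate,
  matching a screening step that precedes the model.
* The alternative `embedding` feature forwards each image through the
  package's own randomly initialized (seeded) VGG-shaped backbone to the
  pooled feature vector and reduces it to its L2 norm. No pretrained
  weights are involved anywhere in the package; a random convolutional
  projection is still a stable exposure-sensitive summary. Mean brightness
  is the default and the recommended choice for exposure artefacts.

## Metrics

Per-class one-vs-rest counts come from the C×C confusion matrix
(`TP_i = counts[i,i]`, `FP_i` column rest, `FN_i` row rest). Macro averages
are means of per-class precision/recall; micro averages pool the one-vs-rest
counts. For single-label classification pooled FP and FN coincide, so
micro-precision = micro-recall = accuracy; the suite asserts this identity
on every computed report. F1 is the harmonic mean of macro precision and
macro recall (a two-class formula generalized; pinned and documented).
Zero-denominator per-class values are defined as 0, logged, and still enter
the macro means. Error is `1 − accuracy` exactly.

## What the synthetic fixtures emulate — and what they do not

The generator writes four texture recipes at 64×64 (configurable):

* **NTL** — smooth low-frequency background (base brightness ~N(0.5, 0.04),
  clipped; two low-frequency sinusoids; mild RGB tint).
* **NST** — background plus a fine grating (period 3–6 px) — high-frequency
  texture without a lesion.
* **LGC** — one bright soft-edged disc (radius 6–14 px, contrast +0.25),
  mask = disc.
* **HGC** — an irregular blob (radial boundary perturbed by ±30% sinusoids,
  contrast +0.35, interior speckle), mask = blob.

These encode exactly the assumptions the pipeline needs to be testable:
class identity is carried by *local, spatially compact* structure (so
saliency maps have a ground truth to localize), clean mean brightness stays
in [0.35, 0.65], and injected outliers (mean brightness ≥ 0.95 or ≤ 0.05,
fraction 10% by default, class labels retained) clear the clean-image IQR
fences by a wide margin. A `separability_probe()` (single convolution +
linear head) confirms each generated set is learnable well above the 1/4
chance level and collapses to chance under label shuffling.

The fixtures deliberately do **not** imitate real cystoscopy appearance —
no vasculature, specular highlights, fluid turbidity, instrument shadows or
inter-patient variation. Passing tests therefore demonstrate that the
mechanics of the pipeline are correct and that each component does its job
on data satisfying its assumptions; they say nothing about clinical
performance on endoscopic images, which requires the real dataset and
full-scale training.

## Problem sizes and defaults

`edl_config()` carries the reference operating point: 32×32×3 CNN input with
the 28→14→10→5 chain, 224×224 XDL input with the 112→56→28→14→7 chain,
10 training epochs, 4 classes. Because a width-1 VGG backbone at 224×224 is
far beyond what a package validation run should cost, `edl_desk_config()`
defines the desk profile used throughout the tests and examples: 100 images
per class at 64×64, CNN/GAN at 32×32, the XDL backbone at 64×64 with channel
width multiplier 1/8, 300 GAN steps, 10 epochs. These sizes were chosen once
as the smallest configuration at which all three members train clearly above
chance and saliency localization is measurable; they are stated here so
results are reproducible, and every number reported by the package is
computed at run time from these settings.

Determinism: every stage derives its RNG seed from the single master seed
(`derive_seed()`), so a fixed seed reproduces fixtures byte-for-byte and
training histories exactly on a fixed platform and BLAS.

## Known limitations

* The engine is CPU-only and unoptimized beyond BLAS matrix products; the
  full-scale configuration (224×224, width 1) is supported but slow.
* The dense head is 400→120→84→K (the widths that actually chain from the
  5×5×16 flatten of the stated convolutional stack); head widths are
  configurable for fidelity experiments with other published settings.
* The class set is configuration (`class_names`), default the four tissue
  classes.
* Per-class GAN quality is not scored (no FID/IS); augmentation value is
  assessed only through the downstream classifier.
* The voting rule consumes stored validation accuracies; if members are
  evaluated on different validation data their accuracies are not
  commensurable. `edl()` guarantees a shared validation split.
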