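---
title: "Semi-supervised image classification with contrastive pretraining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised image classification with contrastive pretraining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Medical image collections typically contain far more unlabeled than labeled
images, because expert annotation is expensive. `litessl` implements a
two-stage semi-supervised strategy for this regime:

1. **Contrastive pretraining.** A light vision-transformer encoder
   $e(\cdot)$ is trained on the *unlabeled* pool with a SimCLR-style
   objective: each image $i$ is mapped by a stochastic augmentation module
   to two views $i'$, $i''$ (a *positive pair*); a projection head
   $p(r) = W^{(2)}\sigma(W^{(1)} r)$ maps the representations
   $r = e(i) \in \mathbb{R}^d$ to embeddings $z$, and the normalized
   temperature-scaled cross-entropy (NT-Xent) loss pulls positive pairs
   together and pushes the other $2(N-1)$ embeddings in the minibatch away,
   using cosine similarity scaled by a temperature $\tau$.
2. **Fine-tuning.** The projection head is discarded, and a deep 12-hidden-
   layer MLP classifier (widths 256, 256, 256, 512, 512, 1024, 1024, 512,
   512, 256, 256, 256, each with ReLU, softmax output) is trained with
   multi-class cross-entropy on a *small labeled subset* of the training
   data.

The split protocol holds out a stratified 20% test set, then divides the
remaining 80% into a labeled subset (the *labeled ratio*: typically 10%,
25% or 50% of the training data) and an unlabeled remainder used only,
without labels, for pretraining.

## Model components and conventions

**Encoder.** An image of size $H \times W \times C$ is cut into
non-overlapping $P \times P$ tiles, giving $N_{patch} = HW/P^2$ flattened
patches of length $P^2 C$. Each patch is projected to a $D$-dimensional
token; a learned class token is prepended and learnable 1-d position
embeddings are added. The token sequence passes through $L$ pre-norm
transformer blocks (multi-head self-attention with $k$ heads of width
$D_h = D/k$, then a two-layer GELU MLP of hidden width $D_{mlp}$, each
sub-layer wrapped in a residual connection around a layer-normalized
input). The representation $r$ is the average over all tokens (class token
included); a class-token readout is available via `pooling = "cls"`. We
default to average pooling because the representation is explicitly defined
as the output of an average pooling layer; the class token is retained in
the sequence so both readouts are possible.

Two printed conventions required interpretation. The patch-count formula is
taken as the standard $N_{patch} = HW/P^2$ (for $96 \times 96$ and $P = 6$,
256 patches), the only reading consistent with the stated
$N \times P^2 \cdot C$ patch-sequence shape. The multi-head output
projection is treated as a separate matrix
$U_{out} \in \mathbb{R}^{(k D_h) \times D}$, distinct from the per-head
$U_{QKV}$, since the dimensions force it.

**Pixel scale.** Augmentations operate on the $[0, 255]$ scale. Before
patching, the encoder maps pixels to $[-0.5, 0.5]$ (divide by 255, subtract
0.5). Centering matters: with non-negative inputs every patch projection is
dominated by the shared DC component of the image, all representations
align along one direction, and both the contrastive loss and any classifier
on the pooled representation start from a nearly collapsed geometry.

**Augmentation module.** Five named stages, in order: per-image min–max
rescaling to $[0, 255]$ (a constant image maps to the lower bound, keeping
the map deterministic); random horizontal flip (probability 0.5; vertical
flip available but off by default since nothing suggests vertical mirroring
is intended); random translation of up to 10% of the side per axis; random
zoom uniform in $[1 - z, 1 + z]$ with $z = 0.15$; and a random per-channel
color affine map (gains within 20%, offsets within 20% of the range),
followed by clipping to the range. Translation and zoom are composed into a
single bilinear resampling pass with reflection padding, avoiding a second
interpolation blur; the two stages still draw independent random
parameters. Magnitudes are conservative values in the range customary in
the contrastive-learning literature and are all configurable.

**NT-Xent.** The batch of $2N$ embeddings is laid out as interleaved pairs
$(2k-1, 2k)$. Similarity is cosine similarity (normalization happens inside
the similarity, not on the embeddings themselves). Each anchor's loss is
$-\log \frac{\exp(s_{i,p(i)}/\tau)}{\sum_{k \ne i} \exp(s_{i,k}/\tau)}$
over the $2N-1$ non-self candidates, and the total is the mean over all
$2N$ anchors — the symmetric sum over both orderings of every pair. With a
single pair the loss is exactly 0, and for $\tau \to \infty$ each anchor's
loss tends to $\log(2N-1)$; both limits are tested. The analytic gradient
through the softmax, the cosine, and the row normalization is verified
against finite differences.

**Gradients.** No automatic differentiation framework is available in this
stack, so every backward pass (NT-Xent, projection head, the full
transformer block including layer normalization and attention, and the deep
MLP) is derived analytically and checked against central finite differences
in the test suite (tolerances 1e-4 to 1e-6; the checks cover every
parameter tensor of a two-block encoder).

**Optimization.** Adam (step size $10^{-3}$ for pretraining, $\beta_1 =
0.9$, $\beta_2 = 0.999$) with no schedule; a robust default for small
models, exposed in the configuration. The last incomplete minibatch of each
epoch is dropped so the $2N$ bookkeeping of the loss stays exact. Biases
are included in the projection head by default (`bias = FALSE` recovers the
pure matrix-product form). Encoder projections are initialized with a
truncated normal (sd 0.02), norm scales at one, shifts at zero. The deep
MLP uses He-normal initialization instead: a 12-layer ReLU stack
initialized at sd 0.02 does not transmit signal and cannot train.

**Classifier conditioning.** Representations entering the deep MLP (and the
linear probe) are standardized feature-wise using training-set statistics
computed with the initial encoder. Pooled transformer representations have
a large common component across images; without standardization the
12-layer head spends its optimization budget fitting that offset and stays
at chance on small labeled sets.

**Fine-tuning.** Whether the encoder should be updated during fine-tuning
is left open by the two-stage design; both modes are provided. The default
configuration updates encoder and head jointly with the encoder at one
tenth of the head's step size; `freeze_encoder = TRUE` trains the head on
frozen representations. The desk-scale experiment harness freezes the
encoder — the standard evaluation protocol when labels are scarce, and the
mode that isolates representation quality.

**Metrics.** Precision, recall and F1 are computed per class from the
confusion matrix and aggregated by macro averaging (equal class weight),
with zero-division cells scored 0 so aggregates stay defined; accuracy is
the trace over the total. `compute_metrics()` is tested against a
brute-force counting oracle.

## The synthetic data generator

`generate_synthetic()` emulates a directory-per-class medical image dataset
at desk scale (default 4 classes of 250 images of $96 \times 96 \times 3$,
mirroring a four-class blood-cell dataset's structure). Class identity is
carried by statistics designed to survive the augmentation family:

* each class has a fixed base texture, an isotropic band-limited Gaussian
  field with dominant frequency $1.5 \cdot 2^{c-1}$ cycles per image
  (adjacent bands two octaves apart stay separated under ±15% zoom), plus a
  mild class hue tint;
* each image blends the base with a freshly drawn field from the same band
  (`pattern_jitter = 0.5` of the power). This keeps same-class images
  distinguishable — without it, every same-class negative in a contrastive
  batch is a near-copy of the anchor, the instance-discrimination task is
  ill-posed, and pretraining is forced toward anti-class features;
* per-image nuisances *inside the augmentation family*: random flip, small
  translation and zoom, per-channel color gains and offsets stronger than
  the class tint, and Gaussian pixel noise (sd 10 on the 0–255 scale).
  Because the nuisance color variation exceeds the tint, raw color is an
  unreliable shortcut, while augmentation-invariant training can learn to
  discard it.

What the generator does *not* emulate: real histology/cytology morphology,
staining chemistry, scanner artifacts, label noise, or class imbalance.
Passing the synthetic study shows the pipeline's mechanics work end to end
and that pretraining extracts augmentation-robust class structure; it does
not certify performance on real medical images.

A sanity oracle verifies the signal exists (simple spectral summary
statistics separate the classes almost perfectly), and a robustness
property verifies that within-class raw-pixel correlation after random
augmentation exceeds between-class correlation.

## Desk-scale study conditions

The acceptance study runs the full pipeline under fixed conditions chosen
once: 4 classes × 250 images; encoder with $D = 64$, $L = 1$, $P = 16$,
$k = 4$, $D_{mlp} = 128$; pretraining for 20 epochs with NT-Xent at
$\tau = 0.1$ and Adam $10^{-3}$ with minibatches of 8 images (16 views) —
small batches give the fixed epoch budget enough optimization steps;
fine-tuning of the deep MLP for 40 epochs (Adam $10^{-3}$ with
half-cosine decay, batch 64) on the frozen encoder; 3 seeds; labeled ratios 10%, 25% and 50%. Pretraining uses
only the unlabeled-training portion of each split, so the ratio sweep
re-pretrains per ratio. Under the nested-subset convention the labeled sets
at increasing ratios contain each other (one permutation per class per
seed), and the held-out test set is identical across ratios and variants.

The reference experiments behind this design run at a very different
scale (25 000 histology images, batch 500, 200 epochs on a GPU); their
headline numbers are not reproducible at desk scale, which is why the
package's acceptance study is property-based: pretraining must beat a
random-encoder probe by a clear margin, the full pipeline must not fall
below the probe, and accuracy must be non-decreasing in the labeled ratio.

## Numerical choices and degenerate inputs

* Rescaling a constant image maps to the lower bound (no division by zero).
* Out-of-bounds samples in translation/zoom are filled by reflection;
  color-affine output is clipped to the pixel range, so the range invariant
  survives the full chain.
* Cross-entropy floors probabilities at $10^{-12}$ inside the log.
* Cosine similarity refuses zero-norm embeddings rather than returning NaN.
* `labeled_ratio = 1` runs without an unlabeled pool (nothing to pretrain
  on; the encoder stays at initialization) and is tagged as such.
* Non-finite losses abort training with a diagnostic rather than silently
  propagating.
* Splits require at least one test and one labeled image per class;
  violations are errors, not warnings.

## Known limitations

* One transformer block and a 64-dimensional representation are deliberate
  desk-scale choices; the encoder is configurable but untested at depth.
* The joint fine-tuning mode propagates gradients through the encoder at a
  fixed relative step size; no layer-wise schedules are provided.
* The synthetic study's difficulty is driven by texture frequency and
  color nuisance; domains whose class signal is shape- or count-based are
  not represented.
* Training is single-threaded CPU linear algebra; at the reference scale
  (tens of thousands of images, hundreds of epochs) a GPU framework is the
  right tool.
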