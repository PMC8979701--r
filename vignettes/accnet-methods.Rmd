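---
title: "Semi-supervised training with augmentation consistency and clustered pseudo-labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised training with augmentation consistency and clustered pseudo-labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accnet)
```

## The problem

Screening tasks such as grading retinal fundus photographs into
normal/abnormal classes have cheap images and expensive labels: expert
annotation of subtle lesions is the bottleneck, while unlabeled images
accumulate freely during routine examinations. `accnet` trains an image
classifier from a small labeled set plus a larger unlabeled pool by
combining two sources of supervision on the unlabeled images:

1. **Augmentation consistency.** The prediction on an unperturbed
   (anchor) image should agree with the predictions on aggressively
   augmented views of the same image. Label-preserving perturbations probe
   the classifier's invariances without requiring any annotation.
2. **Clustered pseudo-labels with a global centroid memory.** Unlabeled
   images receive provisional labels by clustering in the feature space of
   the network itself, and those pseudo-labels supervise further training.

## Model

The classifier is $P(x) = \mathrm{softmax}(F(G(x)))$ where $G$ is a
convolutional feature extractor with parameters $W_G$ and $F$ is a single
linear layer with parameters $W_F$. The package ships two reference
backbones behind one forward/backward interface: a 3-block CNN with
feature dimension $d_f = 64$ for 32×32 images (every test and benchmark in
the package uses this one), and a wider 4-block variant ($d_f = 256$) for
larger inputs. Each block is conv(3×3) → batch norm → ReLU → 2×2 average
pooling, with global average pooling at the end; inputs are centred by
subtracting 0.5 from the [0,1] intensities. Batch normalisation is part of
the block design for the usual reason — without it a small from-scratch
CNN at learning rate 0.001 is optimisation-bound and makes almost no
progress in the training budgets used here — and mirrors the normalised
residual architectures used for this task at full scale. Backprop is
exact throughout (im2col + GEMM convolutions with their adjoints, full
batch-statistics Jacobian through the normalisation), which the test suite
verifies against finite differences.

Inference always uses running normalisation statistics, so it is
deterministic and duplicated inputs map to identical features. Because
training runs here are short (tens to hundreds of updates), the running
statistics average cumulatively over the first updates before switching to
an exponential decay; with the textbook constant-momentum update the
statistics would still be dominated by their initialisation when a short
run ends, and inference-mode predictions would not match what the network
learned.

## Augmentation

The *weak* policy is a random crop covering 80–100% of the area (resized
back) followed by a horizontal flip with probability 0.5 — the standard
mild recipe whose output serves as anchor. The *strong* policy draws
`n_ops = 2` operators at magnitude 10 (on the usual 0–30 scale) from the
standard 14-operator RandAugment pool (geometric + photometric), then
applies a fixed sequence, by default Cutout with a square of 1/4 the image
side. `K = 2` strong views are generated per unlabeled image; K trades
gradient-signal diversity against compute and is a configuration knob.
Geometric operators fill exposed borders by edge reflection so that no
black-corner artifact is introduced for the classifier to shortcut on.
Two operators in the pool (autocontrast, equalize) have no intrinsic
magnitude; they are blended with the identity in proportion to the
magnitude so that magnitude 0 degrades the whole pipeline gracefully to a
near-identity. All randomness flows through explicit stream objects
(`rng_stream()`); nothing touches the global RNG state.

## The four losses

With labeled images $x^l_i$ (plus their weak views) and unlabeled images
$x^u_j$ (plus their strong views), one training step minimises

$$L = L_{lce} + \gamma_1 L_{ac} + \gamma_2 L_{gc} + \gamma_3 L_{pce},
\qquad (\gamma_1, \gamma_2, \gamma_3) = (0.6,\ 0.3,\ 0.8),$$

* $L_{lce}$: cross-entropy over the labeled sub-batch and its weak views;
* $L_{ac}$: mean squared Euclidean distance between each strong view's
  probability vector and its anchor's (the raw unlabeled image's)
  probability vector, with the anchor treated as a constant;
* $L_{gc}$: mean squared distance between the batch-local class centroids
  $c_k$ and the global memory centroids $M_k$;
* $L_{pce}$: cross-entropy of the unlabeled images *and* their strong
  views against the nearest-centroid pseudo-labels, which are constants.

The set-level sums are implemented as means over samples so that the fixed
balance weights keep their meaning regardless of batch composition. All
cross-entropies are computed from log-softmax, never from probabilities.
The distance in $L_{ac}$ is squared-L2 by convention of the
consistency-regularisation literature; an L1 option is available.

## The weight clustering unit

Per batch, class centroids are estimated as softmax-weighted feature
means,
$c_k = \sum_i \delta_k(P_i)\, G(x_i) \big/ \sum_i \delta_k(P_i)$,
so every sample contributes to every class in proportion to its predicted
membership. The global memory is then updated by the damped convex
combination $M_k \leftarrow (1-\eta_k) M_k + \eta_k c_k$ with
$\eta_k = e^{-t_k}$, where $t_k$ counts how many samples were
pseudo-labelled $k$ in the previous batch: classes that are well
represented update their memory slowly, rarely seen classes snap to fresh
evidence. Pseudo-labels are finally assigned by nearest centroid
(Euclidean; ties toward the smaller class index, with distances
accumulated in double precision so the tie-break is reproducible).

Several points are deliberate design decisions where more than one reading
was possible:

* **Local vs global centroids.** Centroids are computed per batch
  (local), and the memory provides the global estimate — the only reading
  consistent with a loss that compares "local" and "global" centroids. An
  optional epoch-end refresh recomputes pool-level pseudo-labels against
  the memory (on by default; it is monitoring only and does not alter the
  training trajectory).
* **Assignment reference.** Pseudo-labels are assigned against the
  memory-smoothed centroids after the batch update (switchable to the raw
  batch centroids): the memory is the lower-variance estimate, which is
  the point of maintaining it.
* **$t_k$ bookkeeping.** "How often class $k$ appeared in the previous
  batch" is read as the count of samples pseudo-labelled $k$; it is the
  only per-(class, batch) quantity that varies meaningfully, and it yields
  the damping behaviour above.
* **Empty classes.** A class whose total soft weight in a batch falls
  below $10^{-6}$ has no usable local centroid: its row is backfilled from
  the memory, excluded from $L_{gc}$, and its memory row is left
  untouched. This prevents NaN centroids at batch size 8.
* **Gradient flow.** Pseudo-label targets and the softmax weights
  $\delta_k$ are constants; gradients flow into $L_{gc}$ only through the
  features inside $c_k$. Letting gradients flow through the targets
  invites the degenerate solution where predictions chase their own
  assignments.
* **Clean statistics for decisions.** Anchor predictions, soft weights
  and pseudo-label assignments are computed with inference-mode
  (running-statistic) forward passes; gradients come from training-mode
  passes. Pseudo-labels should not inherit batch-statistic noise.

## Training loop

Each step draws an 8-image labeled sub-batch and an 8-image unlabeled
sub-batch (both stream sizes equal the configured batch size; one epoch is
a pass over the unlabeled pool). Optimisation uses Adam at learning rate
0.001 with no schedule (SGD + momentum is available); the reference
recipe names the learning rate and batch size but no optimiser, and Adam
is the default a practitioner would reach for. A single root seed fans
out deterministically to initialisation, batching and augmentation
streams, so runs are bit-reproducible and a checkpoint can resume into an
identical trajectory.

The pseudo-label and centroid losses activate only after a supervised
warm-up (default 5 epochs; the labeled cross-entropy and consistency terms
run from the start). The warm-up operationalises the assumption that
pseudo-labelling starts from a *trained* baseline: a from-scratch CNN
after a single epoch still predicts near-uniform probabilities, the
weighted centroids then all collapse onto the global feature mean, and a
pseudo-label loss weighted 0.8 locks the classifier into that collapse.
Five epochs (≈250 updates at the benchmark size) is the smallest round
number at which the warm-started classifier is reliably better than
chance; at the end of warm-up the memory is seeded with the per-class
means of the labeled features, and the per-class counters start at zero so
the first batch update replaces the memory content entirely.

With an empty unlabeled pool the loop reduces exactly — bit for bit — to a
plain supervised cross-entropy loop over the labeled images and their weak
views; the suite asserts this equivalence, and the same supervised loop is
the paired baseline for measuring the semi-supervised gain.

## The synthetic benchmark

`synthetic_spec()` describes class-structured images that emulate the
statistical situation of the screening task: a small labeled set (default
10 per class), a larger unlabeled pool (default 200 per class), 32×32
grayscale images, and optionally an imbalanced positive fraction among the
unlabeled images. Each class has a deterministic base pattern — a
concentric ring texture under a central Gaussian envelope whose *radial
frequency* is class-specific (geometrically spaced between 4 and 10
cycles per image side) — plus i.i.d. Gaussian pixel noise (sd 0.08 in [0,1] units)
and a per-image illumination nuisance (intensity offset, sd 0.04, and
contrast gain, sd 0.10) shared by all classes.

Two generator choices deserve justification:

* **Frequency as the class cue.** The class identity must survive the
  augmentation group, because consistency training explicitly teaches the
  network to ignore whatever augmentation changes. Blob *position* is
  additionally invisible to a translation-invariant GAP-CNN, and
  orientation or polarity cues are scrambled by flips and rotations.
  Radial frequency is invariant to flips and rotations, moved at most ~10%
  by the crops and shears, and untouched by the photometric operators — it
  plays the role that lesion texture plays in real fundus images.
* **What `separation` means.** `separation` is the peak pixelwise
  contrast between two class mean images, in units of the noise standard
  deviation — a local texture signal-to-noise. At the default
  `separation = 6` the class texture is locally clear (peak contrast
  0.48 on a 0.08-sd noise background) but individual labeled sets of 10
  images still under-determine the classifier, which is exactly the regime
  the method targets. Calibrating instead on the whole-image L2 distance
  spreads 6 noise-sd of signal over a thousand pixels (per-pixel SNR ≈
  0.2), and no network of this size trains to a useful accuracy within the
  benchmark budget at learning rate 0.001.

The generator does **not** emulate vessels, lesions, resolution
heterogeneity, label noise, or covariate shift between labeled and
unlabeled pools. Passing the benchmark therefore shows that the training
machinery works — the losses cooperate, pseudo-labels converge to the
hidden truth, the semi-supervised terms add information beyond the labeled
subset — not that the method reaches any particular accuracy on real
fundus data.

Hidden true labels of unlabeled images live in a side channel (a separate
`truth.csv`, never the training manifest) and are used only for
evaluation.

## Evaluation

`confusion_and_metrics()` builds exact integer confusion matrices;
sensitivity is recall on the designated positive (abnormal) class and
specificity is recall on the rest, computed one-vs-rest for multi-class
problems, and reported as missing (never 0) when a class is absent. AUC
uses the midrank convention, so it equals the Mann–Whitney U statistic
divided by $n_+ n_-$ exactly, and the ROC staircase integrates back to the
same number; both are cross-checked against independent implementations in
the tests.

## Problem sizes and budgets

The package's reference benchmark — used by the test suite and the
acceptance script — is the default spec above (420 training images,
separation 6, seed-dependent draws), trained for 30 epochs (1500 steps)
with the tiny backbone, evaluated on a held-out set of 200 freshly
generated images, and repeated over 5 seeds for the paired comparisons
(full model vs supervised baseline vs each ablation variant). These sizes
were chosen as the smallest at which the paired comparisons are stable
across seeds; unit tests use much smaller instances (16×16 images, 2-block
networks, 1–4 epochs).

## Known limitations

* The reference backbones are compact CNNs; no residual-scale network or
  pretrained initialisation is provided, so absolute accuracies on real
  image collections are not comparable to full-scale published systems.
* Binary and one-vs-rest metrics only; no ordinal grading machinery.
* Batch-norm statistics couple the images within a forward pass in
  training mode; all decision-making passes use inference mode, but
  training-mode losses are batch-composition dependent (as is standard).
* The ablation harness regenerates synthetic data per sweep point; it does
  not re-split a fixed external dataset.
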