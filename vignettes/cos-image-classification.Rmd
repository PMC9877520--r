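---
title: "Species identification from correlation-spectroscopy images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species identification from correlation-spectroscopy images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Congeneric mushroom species (the motivating case is eight *Boletus* species
traded as food) have mid-infrared absorbance spectra that are too similar to
tell apart by eye: the same functional groups — water O–H near 3,342 cm⁻¹,
lipid C–H at 2,928/2,855 cm⁻¹, amide I near 1,650 cm⁻¹, polysaccharide and
chitin bands at 1,420, 1,080 and 1,032 cm⁻¹ — dominate every species, and
class differences hide in relative band intensities. Two-dimensional
correlation spectroscopy (2DCOS) spreads those differences over a
wavenumber × wavenumber plane, turning subtle intensity relations into
spatial patterns that an image classifier can exploit.

`cosid` implements the full chain: simulate class-structured FT-MIR spectra,
transform each spectrum into synchronous / asynchronous / integrative
correlation maps, render seven image kinds (the 1D curve, three 2D heatmaps,
three 3D surface projections) as 64×64 RGB rasters, partition samples with
the Kennard–Stone algorithm, and train and compare a radial-basis SVM, an
Alexnet-style CNN and a 12-layer residual CNN.

## The correlation model

For a perturbation matrix $P$ ($m \times n$; rows are perturbation steps,
columns the $n$ retained wavenumbers) the maps are

$$\Phi(v_1, v_2) = \tfrac{1}{m-1}\, P(v_1)^\top P(v_2), \qquad
  \Psi(v_1, v_2) = \tfrac{1}{m-1}\, P(v_1)^\top N\, P(v_2), \qquad
  I = \Phi \odot \Psi,$$

with $N$ the Hilbert–Noda matrix, $N_{jk} = 0$ for $j = k$ and
$1/(\pi(k-j))$ otherwise. $\Phi$ is symmetric (auto-peaks on the diagonal),
$\Psi$ antisymmetric with an exactly zero diagonal (cross-peaks only), and
the integrative map $I$ inherits the antisymmetry.

In the identification pipeline $m = 2$: the first row is the species' mean
spectrum, the second the individual sample. The rows enter **raw** — without
column mean-centering. With $m = 2$, centering makes the two rows exact
negatives of each other and forces $\Psi \equiv 0$ analytically; raw rows
are the only reading that produces the non-degenerate asynchronous
cross-peak structure the transform exists to expose. Spectra are first
truncated to the fingerprint region, read as the closed interval
[400, 1750] cm⁻¹ (338 points on the default 4 cm⁻¹ grid).

## What the synthetic generator emulates — and what it does not

No spectra were available to ship, so the generator is a first-class module:

* **Band structure.** Nine Gaussian bands at the assigned wavenumbers
  (3,342, 2,928, 2,855, 1,650, 1,420, 1,080, 1,032, 650, 550 cm⁻¹) with
  fixed widths; every class shares the set, classes differ by seeded
  height multipliers.
* **Class separation.** A single `separation` scalar scales the multiplier
  spread (`1 + separation × U(−0.35, 0.35)` per band). The default 0.25
  keeps 1D curves of different classes nearly overlapping — which is how
  congeneric FT-MIR spectra actually present, and is the situation the
  correlation transform exists to resolve —
  while any two classes still differ by ≥ 10% in at least one band height
  (enforced by seeded redraw). The default was initially wider (±35%); that
  made the 1D curves visibly distinct between classes, which is not what
  congeneric FT-MIR data look like, and it was narrowed on those grounds.
* **Noise.** Per-scan i.i.d. Gaussian noise (`noise_sd`, default 0.01
  absorbance units — about 1% of the strongest band) plus a per-spectrum
  random baseline tilt (sd 1e-4 absorbance/cm⁻¹) emulating scatter drift.
  Both are drawn only when `noise_sd > 0`, so `noise_sd = 0` requests an
  idealized noiseless instrument and is fully deterministic — which is what
  makes the noise-free invariants testable.
* **Replicates.** Each sample is scanned `replicates` times (default 2) and
  replicate scans are averaged before anything else, mirroring the
  acquisition protocol.

Not emulated: KBr pellet physics, atmospheric CO₂/H₂O subtraction,
instrument line-shape functions, and — importantly — *within-class
biological variability*. All samples of a class share one band profile;
real specimens of one species differ in composition. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that the
qualitative dataset ordering (synchronous maps easiest, raw 1D curves
hardest) emerges under controlled conditions; they do not certify
real-world accuracy levels.

## Rendering

Rendering deliberately bypasses any plotting engine so that rasters are
pure functions of their inputs (byte-identical across re-runs):

* 2D maps are resampled bilinearly to 64×64 and passed through a fixed
  256-entry diverging palette with colour limits symmetric about zero at
  ±max|value| **per image**. Per-image normalization preserves each
  sample's sign structure; it also discards absolute intensity scale,
  which is the price of a bounded colormap.
* 3D kinds orthographically project the (48×48-downsampled) height field
  from a frozen viewpoint (azimuth 45°, elevation 30°), painting cells
  back-to-front, coloured by height with the same symmetric limits.
* The 1D kind draws the absorbance curve (wavenumber descending, per FT-IR
  convention) as a black polyline on white with per-image min–max vertical
  scaling. No axes, ticks or text anywhere — classifier input is signal
  only.

## Partitioning

Kennard–Stone operates on the raw truncated absorbance vectors with
Euclidean distance and no standardization (the algorithm's classical form):
seed with the globally most distant pair, then repeatedly add the candidate
maximizing the minimum distance to the selected set, ties to the lowest
index. Train-side counts round half-up, which reproduces the 7:3 split
1,195/512 of 1,707 samples. Note the algorithm is deterministic, and on
noise-free synthetic data (identical within-class duplicates) it
degenerates — all duplicates tie at distance zero and the test side drains
from the highest indices; use noisy data or a manual split there. Class
mean reference spectra for the correlation transform are computed from the
training population only, so no test-set information leaks into the images.

## Classifiers

* **SVM** (radial basis, libsvm via e1071) on the raw 338-point spectra,
  8:2 split; exhaustive (cost, gamma) grid search by stratified k-fold CV
  accuracy, ties to smaller cost then smaller gamma. Default grid
  $c \in 2^{-5..21}$, $g \in 2^{-15..3}$. The comparison row reports the
  grid-search CV accuracy as its train-side accuracy. Features enter
  unscaled (`scale = FALSE`): absorbance values share a common physical
  unit and scale.
* **Alexnet-style CNN**: conv 96@11×11 + BN + 3×3/2 maxpool (→32),
  conv 256@5×5 + BN + pool (→16), conv 384/384/256@3×3, pool (→8),
  dense 4096, dense 4096, dense K. Pools use same-padding, so the spatial
  trace is exactly 32/16/8. Trained with Nesterov momentum 0.9,
  staircase learning rate 0.01 × 0.99^(epoch div 3), and early stopping on
  test accuracy (min_delta 0.001, patience 5). The dense width is
  configurable: the two 4096-unit layers hold ~84M weights, and the
  pipeline's default config trains with `dense_units = 1024` as its
  desk-scale choice.
* **Resnet-12**: stem 3×3 stride-2 conv + BN + ReLU, then two projection
  (conv) residual blocks and three identity blocks interleaved
  (projection wherever spatial or channel dimension changes), widths
  16→32→64, global average pooling, softmax head — 12 weight layers
  counting the stem, the ten main-path block convolutions and the head
  (shortcut 1×1 convolutions excluded, standard ResNet counting). Trained
  with plain SGD, lr 0.01, weight decay 1e-4, fixed epoch budget
  (default 15). The stride-2 stem and the stage widths are this package's
  choices and keep 64×64 CPU training fast.

### Numerical choices

The engine stores activations as (H, W, C, N) double arrays; convolution
and pooling run through im2col + BLAS kernels verified against literal
nested-loop oracles and central-difference gradients. Batch-norm uses
batch statistics in training and running statistics in evaluation; because
desk-scale epochs contain only a handful of minibatches, the exponential
running average lags the fast-moving activation statistics badly, so after
each epoch the running moments are recomputed exactly over the training
set in one pass (precise-BN recalibration). Weight decay applies to
convolution/dense weight matrices only, never to biases or BN parameters.
Initialization is He-normal from the config seed; batch shuffling derives
from the same root seed via named substreams, so training is exactly
reproducible.

Early stopping keeps a patience counter that only improvements larger than
`min_delta` over the best monitored value reset; the reported model is the
one at the earliest epoch attaining the maximum test accuracy, and the
confusion matrix is computed from it. The comparison table's loss column
reports the minimum epoch loss; the final-epoch loss is also retained on
the fit.

## The comparison

A full run trains 15 models — the SVM on spectra plus each CNN on all
seven image kinds — and emits one row per model: stopping epoch, minimum
loss, train accuracy, test accuracy, elapsed seconds. Sensitivity means
per-class recall (diagonal over row sum, rows = true class); classes
absent from the test set are flagged rather than silently dropped.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely from synthetic
data at sizes chosen for a single desktop CPU: the image-count and split
identities at the full 1,707-sample size (cheap, no training), the
15-model enumeration at 8 classes × 5 samples with 2-epoch budgets, and
the class-recovery experiment at 8 classes × 200 samples with the 15-epoch
residual-network budget on synchronous-2DCOS versus 1D images. At those
frozen conditions the residual network reaches test accuracy ≥ 0.95 on
synchronous maps and strictly exceeds its own 1D-curve accuracy,
reproducing the qualitative dataset ordering.

## Known limitations

* With $m = 2$ the correlation maps are deterministic functions of
  (sample, class mean); they re-encode rather than add information. The
  benefit over the 1D curve is representational — smooth intensity
  patterns survive 64×64 rasterization better than thin curves do.
* The 8:2 split of 1,707 samples gives 1,366/341 under round-half-up;
  no single rounding rule yields a 1,367/340 partition, so that pairing
  is not chased.
* Wall-clock timings are hardware-bound and never compared.
* The dashboard/visualization layer of the original workflow is out of
  scope.
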