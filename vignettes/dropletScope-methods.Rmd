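---
title: "Recognizing cell-encapsulated droplets: models and methods"
author: "dropletScope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing cell-encapsulated droplets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletScope)
```

## The problem

Droplet microfluidics discretizes a cell suspension into picoliter
reactors. For single-cell assays one wants exactly one cell per droplet,
but passive encapsulation is governed by Poisson statistics: if the mean
cell load per droplet (CPD) is $\lambda$, the probability of $k$ cells in
one droplet is

$$\rho_k = \frac{\lambda^k}{k!} e^{-\lambda},$$

so at best $1/e \approx 36.8\%$ of droplets carry exactly one cell
(at $\lambda = 1$), at which point $26.4\%$ already carry two or more.
Practical protocols therefore run dilute ($\lambda \approx 0.2$–$0.3$) and
need continuous monitoring: how many droplets were produced, how many hold
one cell, how many hold several. `dropletScope` implements a two-stage
image-recognition pipeline for that monitoring task on brightfield
micrographs of pooled droplets, plus the Poisson analytics used to judge
encapsulation performance.

The two stages are:

1. **ASTM** (adaptive-scale template matching) proposes droplet bounding
   circles from the binarized foreground of a frame.
2. **WSCNet** (weakly supervised counting network), a seven-convolution
   two-branch network, filters false proposals and produces, per droplet, a
   nonnegative *density map* whose integral estimates the encapsulated cell
   count and whose leading maxima localize the cells — although it is
   trained only with droplet-level labels (*empty*, *single*, *at least
   two*), never with cell positions.

## Stage 1: adaptive-scale template matching

The frame is binarized with a global Otsu threshold, with polarity chosen
so the (dark) droplets become foreground, and interior holes are filled so
droplets are solid disks. Frames with no real foreground are recognized by
the Otsu separation criterion: the between-class variance of the split must
explain at least 75% of the total intensity variance, a level that a
single noise mode cannot reach (splitting a pure Gaussian at its mean
explains only $2/\pi \approx 64\%$), while any frame with a genuine
droplet phase clears it comfortably.

The matching response of a binary disk template $T$ of diameter $r$ at a
pixel is the fraction of the template area covered by foreground — a
normalized correlation of the mask with the disk kernel, computed here by
FFT (`EBImage::filter2`), with values in $[0, 1]$. The search starts at a
template diameter `rInit` above the largest expected droplet and proceeds
downward. At each scale, every local maximum (8-neighborhood, raster-order
tie-break) at or above the threshold $\sigma = 0.98$ becomes a proposal
whose center is the pixel and whose diameter is the current scale;
mutually non-overlapping maxima are accepted per pass, their foreground is
erased, and the same scale is re-searched until the best response falls
below $\sigma$. The scale then shrinks adaptively, capped at $0.95\, r$ so
the sequence always contracts; the search ends below `rMin` or when the
foreground is exhausted. A final non-maximum suppression on circle IoU
(threshold 0.3) removes residual duplicates.

The adaptive step deserves a precise statement. The best response
$D_{max}$ at scale $r$ corresponds to a covered foreground area of
$\frac{\pi r^2}{4} D_{max}$ — an equivalent disk of diameter
$r\sqrt{D_{max}}$ — so the next scale is $r_{next} = \sqrt{D_{max}}\, r$.
The frequently quoted multiplicative form $r_{next} = D_{max}\, r$
overshoots: for an isolated droplet of diameter $d$ seen from scale $r$,
$D_{max} = (d/r)^2$ and the multiplicative step jumps to $d^2/r < d$,
skipping the droplet's own scale and mis-sizing it (an effect directly
visible in the isolated-disk unit test); the square-root step lands on $d$
exactly. Similarly, an accepted circle erases foreground out to one shrink
step beyond its own radius, because the quantized scale grid only brackets
the true radius from below — without the margin, leftover crescent slivers
re-fire as spurious small proposals.

Design choices worth stating:

* **Erase-after-accept.** A droplet whose circle was accepted at one scale
  must not fire again at a smaller scale; erasing its foreground enforces
  that directly, with NMS as a safety net. We batch-accept all
  non-conflicting maxima of a scale pass before re-computing the response;
  the alternative (recompute after every single acceptance) costs one FFT
  per droplet and changed nothing measurable on synthetic scenes.
* **Shrink clamp.** The adaptive step $r_{next} = D_{max} r_{cur}$ stalls
  as $D_{max} \to 1^-$; the 0.95 cap guarantees progress. With droplet
  CVs below ~10% the 5% grid also bounds the radius quantization error,
  keeping circle IoU against truth above 0.8.
* **Defaults.** $\sigma = 0.98$; `rInit = 40` px (≈1.5× the largest
  droplet diameter of the default scene model); `rMin = 8` px, below the
  smallest droplets the emulated optics produce (diameters ~14–40 px).

## Stage 2: the weakly supervised counting network

### Architecture

Seven 3×3, stride-1, same-padded convolutions in total — a deliberate
constraint (the model must stay small enough to retrain at the bench):
a shared trunk of four layers (8, 8, 16, 16 channels), then a counting
head of three layers (8, 8, 1) ending in a ReLU so the single-channel
density map $D$ is nonnegative and at full input resolution. The
classification head reads the trunk through global average pooling into a
linear 2-class readout (droplet vs. false-positive proposal); pooling and
a linear map are not convolutions, so the seven-layer budget is respected.
The whole model has about 6,000 parameters — orders of magnitude below a
34-layer residual classifier — and `show()` on a `WSCNet` prints the
exact count.

### Losses

With $D_{sum} = \sum_{ij} D_{ij}$ and $D_{max} = \max_{ij} D_{ij}$:

* truncated count prediction
  $f(D) = D_{sum}$ if $D_{sum} < 2$, else $2 + \gamma D_{sum}$, with
  $\gamma = 0.001$. The *multiple* label only asserts "at least two", so
  predictions beyond 2 should not be punished; the small slope keeps a
  gradient alive.
* peak regularizer $\psi(D) = \max(D_{max} - 1, 0)$. Without it the
  truncation lets the network dump unbounded mass into one pixel for
  multicell droplets; capping per-pixel density at ~1 forces one unit of
  mass per cell, which is what makes the maxima localize cells. (The
  source derivation prints the inactive branch of this penalty with an
  inconsistent condition; the regularizer is defined on the maximum, and
  that is what is implemented.)
* counting loss $L_{count} = (f(D) - y)^2 + \psi(D)$ on droplet patches
  only, $y \in \{0, 1, 2\}$.
* total loss $L = L_{class} + \omega L_{count}$, $\omega = 1$, with
  $L_{class}$ the cross-entropy of the background/droplet classifier. The
  printed combination in the source ($\omega L_{count} + (1-\omega)
  L_{count}$) is degenerate and would silence the classification branch at
  $\omega = 1$ even though that branch is used at inference; the additive
  form trains both branches for any $\omega > 0$ and is the package's
  documented reading.

At inference the density map is consulted only when the classifier says
*droplet*: the predicted count is $\lfloor D_{sum} + 0.5 \rfloor$, that
many leading density maxima (greedy, 3 px minimum separation) are the cell
locations, and the droplet is re-classified into empty/single/multiple by
the nearest count, with boundaries exactly at $D_{sum} = 0.5$ and $1.5$
(ties toward the smaller count).

### Implementation and training

No deep-learning framework is part of this package's dependency stack; the
forward and backward passes are implemented in compiled code
(Rcpp/RcppArmadillo) with im2col + BLAS matrix products, and the analytic
gradients are verified against central finite differences in the test
suite. Training is mini-batch Adam, seeded end to end (initialization,
shuffling; no augmentation); the validation loss is evaluated every epoch,
the learning rate halves after `patience` epochs without improvement, and
the best-validation weights are returned.

Two numerical choices matter enough to document:

* **Input polarity.** Patches are normalized to $[0,1]$ *inverted*:
  $(255 - I)/255$, so the bright oil background sits near 0 and absorbing
  structures (rims, cells) carry positive signal. With the raw polarity the
  counting branch reliably converged to an input-independent constant map
  (the marginal label mean) within the short training budgets used here;
  with inverted patches the same budget separates the classes cleanly.
* **Density-layer initialization.** The final bias starts at 0, not at a
  positive value: a positive start puts $D_{sum}$ of a 32×32 map deep into
  the truncated branch where the gradient is only $O(\gamma)$, and
  training crawls.
* **Learning rate at desk scale.** `TrainConfig` defaults to the
  conservative $10^{-4}$ with plateau-halving. The desk-scale experiments
  in this package's tests train for only a few hundred optimizer steps
  (~12,000 patches, batch 256, ≤ 30 epochs), where $10^{-4}$ cannot leave
  the constant-map plateau; they therefore pass `learningRate = 5e-3`,
  chosen from prototype loss curves on generator output.

## The synthetic scene generator

There is no public corpus of annotated droplet micrographs, so the package
generates its own, with full ground truth (circles, per-droplet cell
centroids, category labels). A scene emulates the statistical and
geometric structure the recognizers care about:

* 640×480 frames, ~150 droplets (the real acquisition regime: VGA frames
  averaging ~190 droplets each);
* droplet diameters from a truncated normal, default mean 22 px, CV 8% —
  matching 14–26 µm droplets at the working magnification, where reported
  monodispersity is CV ≲ 4–8%;
* centers placed by rejection sampling with pairwise distance at least
  $(r_1 + r_2)(1 - 0.15)$, emulating adherent monolayers without heavy
  occlusion;
* per-droplet cell counts $\sim$ Poisson($\lambda$), default
  $\lambda = 0.26$ (the >20% single / <3% multicell operating regime);
  cells uniform in the inner 80% of the disk, ≥3 px apart, so 4–10 px
  valid-radius localization remains well-posed;
* appearance: bright background (200), slightly darker interior (−30),
  2 px dark rim (−110), cells as dark Gaussian blobs (−120 peak, diameter
  4–8 px), additive Gaussian noise (SD 4), rounded to the 8-bit grid so
  the in-memory frame equals its PNG serialization.

What the generator does *not* emulate: optical blur and shading fields,
out-of-focus droplets, debris, cell aggregation at high $\lambda$, and
deformed (non-circular) droplets. Tests passing on these scenes therefore
demonstrate the correctness and internal consistency of the algorithms
under the stated geometry and Poisson loading, not performance on any
particular microscope's data.

Patch datasets for training are drawn from scenes at $\lambda = 1$, not at
the default operating $\lambda$: training wants balanced categories (the
original curated training table is roughly balanced across
background/empty/single/multiple), and at $\lambda = 0.26$ multicell
droplets are 2.8% of all droplets, which would require ~700 scenes per
3,000 multicell patches. Patches default to 32×32 from a crop window of
2.4× the circle radius: for 14–40 px droplets the native crop is 17–48 px,
so 32 px is the natural scale (and keeps the compiled network fast);
both size and crop factor are configurable and recorded in checkpoints.

## Poisson analytics

`encapsulationRates()` tabulates $\rho_0$, $\rho_1$,
$1 - \rho_0 - \rho_1$ and the conditional single-cell rate
$\rho_1 / (1 - \rho_0)$ (undefined at $\lambda = 0$ and returned as `NA`
rather than silently NaN). `estimateCPD()` inverts the zero term,
$\hat\lambda = -\ln(1 - M^d/N^d)$, from detected ($N^d$) and positive
($M^d$) droplet counts; the all-positive edge case surfaces as `Inf` with
a warning. `cpdFromDensity()` computes the physical expectation
$\lambda = D_{cell} \cdot \frac{4}{3}\pi R^3$ with explicit units — note
this is density *times* volume; the phrase "density divided by volume"
that sometimes accompanies this quantity is dimensionally impossible, and
the estimator and the physical formula are deliberately kept as two
separate functions that are never conflated.

## Evaluation

Detections are matched to truth circles one-to-one, greedily in descending
circle IoU (computed analytically from the lens area; the rasterization
oracle lives in the tests). Greedy matching was chosen over optimal
assignment for transparency and speed; on instances small enough to
enumerate, the tests bound its deviation from the exhaustive optimum.
Category-aware F1 books a matched pair with disagreeing categories as a
false positive of the predicted category *and* a false negative of the
true one; unmatched circles count against their own category.
Localization uses the valid-area protocol: a prediction is a true positive
iff its greedy nearest-distance match lies within an $x$-px radius of the
annotated centroid ($x$ evaluated over 4–10 px). Counting error is the
mean relative error over droplets with positive true count; zero-count
droplets are excluded and their number reported. `poissonFitRSS()` scores
observed rate–$\lambda$ points against the theoretical curves (RSS) and,
given raw counts, runs a $\chi^2$ goodness-of-fit with sparse tail bins
pooled.

## Problem sizes used in the shipped tests

The test suite and acceptance script run entirely on generated data, at
sizes chosen so the whole suite stays desk-scale: the detection benchmark
uses 20 frames (~3,000 droplets); Poisson-fidelity checks use ~10,500
simulated droplets; the network is trained once per run on 12,000 patches
(3,000 per category, batch 256, 10 epochs — a few hundred optimizer
steps) and shared across the recognition, localization and
parameter-recovery tests. Category F1 is measured end-to-end (detector +
network) on six held-out frames at $\lambda = 0.5$, against the ≥ 0.88
mean-F1 level, and localization precision on held-out multicell patches
against the ≥ 89% level at a 10 px radius.

## Known limitations

* The generator's appearance model is deliberately minimal; domain shift
  to real optics (blur, shading, debris) is untested by construction.
* ASTM assumes near-circular droplets and a bimodal intensity histogram;
  heavily occluded or deformed droplets violate both.
* The counting branch truncates at two: counts above ~3 are extrapolation
  through the $\gamma$ slope, and crowded multicell droplets (cells closer
  than the 3 px peak separation) can merge into one maximum — the same
  failure mode the weak-label training itself cannot penalize.
* Greedy matching and greedy peak picking are order-dependent at exact
  ties; ties are broken deterministically (raster / scan order) and are
  measure-zero on noisy data.
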