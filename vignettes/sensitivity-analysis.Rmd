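---
title: "Probing segmentation robustness with sensitivity maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing segmentation robustness with sensitivity maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segsense)
```

## The problem

Deep-learning segmenters for 3D medical images often perform very well on
data that looks like their training sample and degrade sharply on data that
does not — different scanner, different intensity calibration, different
head pose. `segsense` quantifies that fragility directly instead of
inferring it from aggregate test scores: it sweeps a test volume over a grid
of controlled perturbations (rigid rotations about the x- and y-axes, or
linear intensity rescalings), runs the segmenter on every perturbed volume,
and scores each output with the Sørensen–Dice coefficient

$$\mathrm{DSC} = \frac{2\,|V_{\mathrm{ref}} \cap V_{\mathrm{pred}}|}
{|V_{\mathrm{ref}}| + |V_{\mathrm{pred}}|},$$

yielding a *sensitivity map*: DSC as a function of the perturbation
parameters. A flat map means a robust model; a sharply peaked map means the
model only works near one operating point; a peak displaced from the
unperturbed point diagnoses an orientation (or intensity) *sampling bias* of
the training data — the argmax offset names the realignment that would
optimize performance.

The same workflow runs with or without ground truth. With ground-truth
labels, each perturbed segmentation is compared against the identically
perturbed labels. Without ground truth, all segmentations are
back-transformed into the unperturbed space and a STAPLE
expectation–maximization consensus over them serves as the reference.

## The three-step engine

`run_sensitivity()` executes, for every point of a `parameter_grid()`:

1. **Modify** — the pristine input volume (never a previously perturbed
   one, so errors cannot accumulate) is rotated with trilinear
   interpolation for the image and nearest-neighbor for the labels, or
   intensity-transformed as $i \mapsto s\,i + o$ (scale before offset).
   4D diffusion volumes rotate every 3D sub-volume identically and the
   gradient table is co-rotated with the same matrix.
2. **Segment** — the user-supplied `segmenter()` is called on the modified
   image. The engine only requires the contract: same spatial shape out,
   non-negative integer labels.
3. **Evaluate** — per-label Dice against the reference; scores land at the
   grid coordinates.

Three grids are predefined because their design constants matter:

* `rotation_grid_case1()` — x/y rotations over the full circle,
  $[-180:20:180]°$, $19 \times 19 = 361$ points, for locating gross
  orientation mismatches (e.g. a test cohort stored in a different
  anatomical orientation code).
* `intensity_grid_case1()` — 17 scale factors from $1/5$ to $5$ in the
  non-linear series $1/5, 1/4.5, \dots, 1/1.5, 1, 1.5, \dots, 5$ crossed
  with 17 offsets from $-3$ to $3$ in steps of $3/8$ (289 points), designed
  for volumes z-normalized to zero mean and unit variance
  (`normalize_volume()`), where an offset of 3 moves the mean by three
  standard deviations.
* `rotation_grid_case2()` — $\pm 16°$ in $2°$ steps ($17 \times 17 = 289$),
  for fine-grained pose bias around the native orientation, typically with
  `center_mode = "mass_center"`.

### Conventions that had to be fixed

The rotation composition for two-axis grids is not canonical anywhere, so
one convention is fixed and logged into every map's provenance: extrinsic
rotations about the fixed world axes, x first, then y, then z; right-handed;
counter-clockwise positive looking down the axis. The inverse of a combined
$(x, y)$ rotation is therefore $(-y)$ then $(-x)$. Gradient co-rotation uses
the identical matrix, which is the only internally testable requirement.
Rotation centers resolve as the volume center (default), the
intensity-weighted center of mass, or an explicit point in mm; voxel indices
are 0-based and geometry is carried in mm via the voxel size.

Labels are resampled nearest-neighbor — trilinear interpolation would
invent fractional label values — and out-of-field voxels pad with 0
(background) for both image and labels, the only padding that keeps Dice
denominators meaningful. Identity rotations return the input array
untouched, so the identity grid point is guaranteed to equal the direct
`dice(seg(image), labels)` with no resampling round-trip error.

### Degenerate Dice cells

When a structure leaves the field of view, reference and prediction can both
be empty and Eq. DSC is $0/0$. Such cells score 1.0 (the two segmentations
agree there is nothing) but carry a degenerate flag, and `aggregate_maps()`
excludes flagged cells from its coordinatewise means so that averaged maps
stay comparable across subjects. Empty-versus-nonempty is 0 by the formula.

### Summaries and tie-breaking

`map_summary()` reports the map mean and standard deviation (population
convention, matching how a map of $N$ cells is a complete enumeration, not
a sample), the maximum, and the argmax offset from the grid's identity
point (0 on angle/offset axes, 1 on the scale axis). Tied maxima resolve to
the tied point *closest to the identity*, then first in array order: a
perfectly flat map therefore reports zero bias, which is the scientifically
meaningful reading (reporting the grid corner, as a pure first-in-order rule
would, would manufacture a spurious bias diagnosis). The tie count is
reported so a plateau is visible in the summary.

## STAPLE consensus

When no ground truth exists, the reference is estimated from the
segmentations themselves with binary STAPLE (Warfield et al., 2004): a
hidden true segmentation $T$ and per-rater sensitivities $p_k$ and
specificities $q_k$ are estimated by EM. The E-step computes voxelwise
posteriors $W_i = P(T_i = 1 \mid D, p, q)$ from a global foreground prior
(`"auto"` = mean foreground fraction across raters); the M-step re-estimates
$(p_k, q_k)$ from the posteriors. Initialization at $p_k = q_k = 0.9999$ is
the canonical near-perfect start and avoids the label-swapped fixed point;
iteration stops when the mean absolute posterior change drops below $10^{-6}$
(at most 100 iterations); the incomplete-data log-likelihood is tracked and
non-decreasing. Consensus masks binarize at probability 0.5 (configurable).
Multi-label volumes run binary STAPLE per label ID.

Two caveats are part of the method's contract. First, consensus quality
requires that a sufficient share of the input segmentations is meaningful;
the test suite demonstrates the consensus degrading once random masks
dominate the rater set. Second, two exactly complementary raters under a
uniform prior land on the symmetric fixed point — every posterior exactly
$1/2$, no usable consensus — which the implementation reaches (and the suite
documents) rather than masking. In sensitivity analysis the engine requires
all raters in one space: segmentations from rotated configurations are
back-transformed with the inverse rotation (nearest-neighbor), and voxels
that left the field of view in any configuration are excluded from both the
consensus estimation and the scoring through a validity mask.

## Training-time augmentation samplers

The package also implements the two augmentation families whose effect the
sensitivity maps are designed to visualize:

* **Rotation augmentation.** Type 1 mirrors the volume independently along
  each image axis with probability 0.5; type 2 additionally draws one
  rotation of 0°, 30° or 50° about the x-axis (uniformly over the choice
  set), the x-axis because natural head motion is mostly nodding. Mirroring
  applies before the rotation; for an x-axis rotation the two orders
  generate the same operator set, so the choice is conventional.
* **Histogram-landmark intensity augmentation.** Histogram landmarks are the
  intensity quantiles at 12.5 %–87.5 % in steps of 12.5 % (7 landmarks,
  linear interpolation between order statistics, computed over all voxels).
  For every *ordered* pair of training datasets a second-degree polynomial
  transfer function $I' = C_1 I^2 + C_2 I + C_3$ is least-squares fitted
  between their landmark vectors; ordered pairs because the transfer is
  directional. The pooled coefficients are summarized by sample mean and
  sample standard deviation (ddof 1) — the normal-distribution
  parameterization — and training-time draws sample each coefficient
  independently from its normal. Identical training sets collapse to the
  degenerate model mean $(0, 1, 0)$, std $(0, 0, 0)$, whose draws are the
  identity transform exactly.

## What the synthetic fixtures emulate — and what they do not

`make_phantom()` generates the test volume every stage runs on: a tilted
anisotropic ellipsoid (semi-axes 0.33, 0.20, 0.12 of the volume size, tilted
by fixed generic angles) with an attached off-axis spherical protrusion,
classwise intensity means plus Gaussian noise (default σ = 0.1 against a
background/foreground contrast of 1). The tilt and the protrusion are
load-bearing: they break every mirror and rotational self-symmetry, so a
non-identity grid rotation overlaps the original at DSC < 0.9 and
template-matching toys genuinely discriminate orientation. The foreground
occupies a few percent of the volume and stays several voxels inside the
field of view under any rotation about the center.

Two toy segmenters have *designed* sensitivities. The intensity-window
segmenter (threshold plus largest 6-connected component) is rotation-robust
but collapses when scale/offset moves the tissue class out of its window —
its intensity map shows the band structure expected of a model trained
without intensity augmentation, with a perfect score at the identity. Note
its honest quirk: a linear window is scale-compression-invariant, so a
plateau of perfect scores exists where compressed intensities land inside
the window; the argmax tie-breaking reads such plateaus as zero bias. The
template-matching segmenter returns the labels of its best-correlating
template orientation: with `"identity_only"` it emulates a model trained in
one pose (sharply peaked rotation map); with a bank of orientations it
emulates a rotation-augmented model (flatter map, strictly lower variance —
the flattening signature). Building the template from a pre-rotated phantom
injects a known training-pose bias, which the argmax offset recovers to
within one grid step.

The phantoms deliberately do not model MRI physics: no bias fields, no
partial-volume tissue mixtures, no diffusion signal, no anatomy. Passing
tests therefore demonstrate the *machinery* — transforms, metrics, EM,
bookkeeping — under known ground truth, not performance of any real
segmenter on real data.

## Numerical choices

* Volume-wise normalization uses the population variance so the normalized
  volume has unit variance exactly; it is idempotent to $10^{-9}$.
* Landmark quantiles use linear interpolation between order statistics
  (R's default type 7), the dominant convention and a testable one.
* The transfer-function fit solves the $n \times 3$ Vandermonde system by QR;
  with $\ge 3$ distinct landmarks it is exact on quadratically generated
  targets to $10^{-9}$.
* Gradient vectors off unit norm by $\le 10^{-3}$ are renormalized, beyond
  that rejected; $b = 0$ rows may be zero vectors.
* All samplers take an explicit integer seed and restore the caller's RNG
  state, so runs are reproducible and composable.

## Problem sizes used in the shipped checks

The shipped test-suite and the acceptance script run the full pipeline at
phantom sizes 32³–64³ with full 17 × 17 intensity grids and 5 × 5 to 7 × 7
rotation sub-grids; the demo (`run_demo()`) uses 48³ by default. These sizes
were chosen so every qualitative pattern — intensity band, rotation peak,
bank flattening, bias recovery, STAPLE parameter recovery within ±0.02 —
is exercised in minutes on a single CPU while leaving boundary effects
(thin-structure nearest-neighbor resampling at 24³ and below) out of the
tested regime.

## Known limitations

* Heat-map rendering is 2-D only; higher-dimensional grids are computed but
  must be sliced for display.
* STAPLE here is the global-prior, spatially uniform, hard-rater binary
  variant; no MRF regularization, no probabilistic raters.
* The rotation model is rigid; elastic deformation, scaling and noise
  perturbations are out of scope.
* In STAPLE reference mode the maps are relative to a reference estimated
  from the very segmentations being scored, so they are qualitative;
  absolute values are not comparable across segmenters the way
  ground-truth-mode maps are.
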