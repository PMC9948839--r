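# segsense

Performance sensitivity analysis for 3D (and 4D diffusion-weighted) medical
image segmentation.

Modern segmentation models — CNNs above all — can be strikingly sensitive to
properties of their input that a human reader barely notices: head pose,
intensity calibration, scanner-specific contrast. `segsense` measures that
sensitivity directly. It systematically perturbs a test volume over an
N-dimensional parameter grid (rigid x/y rotations; intensity scale and
offset), runs *any* user-supplied segmenter on each perturbed volume, and
scores every output with the Sørensen–Dice coefficient

```
DSC = 2 |V_ref ∩ V_pred| / (|V_ref| + |V_pred|)
```

against ground-truth labels or, when none exist, against a STAPLE
expectation–maximization consensus of the segmentations themselves. The
result is a **sensitivity map**: DSC as a function of the perturbation
parameters. Flat maps mean robustness; a peak displaced from the identity
point diagnoses a training-sample bias, and the argmax offset names the
realignment that would fix it.

The package is aimed at people who evaluate or deploy segmentation models —
it never trains one. It additionally ships the two training-time
augmentation samplers whose effect such maps visualize (mirroring/discrete
x-rotation augmentation, and histogram-landmark polynomial intensity
augmentation), plus a synthetic phantom module so the entire pipeline runs
and is testable without any external data.

## What's inside

| Area | Functions |
| --- | --- |
| Data model & I/O | `labeled_volume()`, `read_labeled_volume()`, `write_labeled_volume()`, `read_gradient_scheme()`, `normalize_volume()` |
| Metrics | `dice()`, `dice_per_label()` |
| Transforms | `rotate_volume()`, `mirror_volume()`, `apply_intensity_affine()`, `polynomial_intensity_transform()`, `rotate_gradient_scheme()` |
| Augmentation | `extract_landmarks()`, `fit_transfer_function()`, `build_transfer_model()`, `sample_intensity_augmentation()`, `sample_rotation_augmentation()` |
| STAPLE | `staple_consensus()`, `staple_consensus_multilabel()`, `simulate_raters()` |
| Sensitivity engine | `rotation_grid_case1()`, `intensity_grid_case1()`, `rotation_grid_case2()`, `segmenter()`, `run_sensitivity()`, `aggregate_maps()`, `map_summary()`, `plot_sensitivity_map()` |
| Synthetic fixtures | `make_phantom()`, `make_threshold_segmenter()`, `make_template_segmenter()`, `run_demo()` |

Volumes read and write as NIfTI-1/2 (via RNifti), gradient tables as FSL
bval/bvec text, scores as tidy TSV, provenance as JSON.

## Worked example

```r
library(segsense)

# a synthetic test volume: tilted ellipsoid + protrusion, noisy image
v <- make_phantom(phantom_spec(shape = c(32, 32, 32), rng_seed = 1))
v$labels[v$labels == 2L] <- 1L

# a toy segmenter: intensity window + largest connected component
seg <- make_threshold_segmenter(0.5, 1.5)

# sweep the full 17 x 17 intensity scale/offset grid
map <- run_sensitivity(v, seg, intensity_grid_case1(),
                       reference_mode = "ground_truth")
s <- map_summary(map)
map$scores["1", "0", "1"]   # DSC at the unperturbed point
s$mean; s$sd; s$argmax
```

prints

```
<sensitivity_map> ground_truth 'threshold[0.5,1.5]' on 'phantom_seed1':
  289 points x 1 labels, mean DSC 0.100 +/- 0.277
identity DSC: 1.000
map mean 0.100 +/- 0.277, argmax at scale=1 offset=0
```

Read: this segmenter is perfect on unperturbed input (identity DSC 1.0) and
its best operating point *is* the unperturbed point (argmax at scale 1,
offset 0 — no intensity bias), but performance collapses over most of the
intensity plane (map mean 0.10), exactly the fragility signature of a model
with a hard-coded intensity window. `plot_sensitivity_map(map)` renders the
heat map.

Without ground truth, the STAPLE route estimates the reference from the
segmentations; on five simulated raters with known performance:

```r
truth  <- v$labels > 0
raters <- simulate_raters(truth, sens = c(0.95, 0.9, 0.85, 0.8, 0.75),
                          spec = rep(0.99, 5), rng_seed = 2)
st <- staple_consensus(raters)
```

```
<staple_result> 5 raters, 6 iterations (converged), prior 0.039
  sensitivity p_k: 0.959 0.893 0.850 0.807 0.756
  specificity q_k: 0.989 0.990 0.991 0.990 0.990
consensus vs truth DSC: 0.992
```

The EM recovers each rater's generating sensitivity/specificity to within
±0.01 and the consensus mask agrees with the hidden truth at DSC 0.99.

A full end-to-end study (phantom → grids → toy segmenters → maps →
summaries → STAPLE), writing NIfTI/TSV/JSON/PNG outputs, is one call:

```r
run_demo("demo_out", shape = 48, seed = 1)
```

or from a shell, along with the other subcommands (`grid`, `run`,
`aggregate`, `summary`):

```sh
Rscript inst/cli/segsense.R demo --out demo_out
```

## Plugging in a real segmenter

Wrap anything callable as `segmenter(function(image, scheme = NULL) ...)`
returning an integer label array of the input's spatial shape — e.g. a
function that writes the image to disk, shells out to a trained network, and
reads the result back. For diffusion data, pass the `read_gradient_scheme()`
table to `run_sensitivity()`; it is co-rotated and handed to your segmenter
at every grid point.

## Vignette

`vignettes/sensitivity-analysis.Rmd` documents the model and conventions:
rotation composition and handedness, padding and label resampling, the
degenerate-Dice convention, the STAPLE EM details, the augmentation
samplers, what the phantoms do and do not emulate, and known limitations.
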