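---
title: "Radial-scanning shape signatures and 4D classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial-scanning shape signatures and 4D classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscan)
```

## The problem

Malignant lung nodules tend to have irregular, spiculated boundaries,
while benign nodules are usually smooth. `radscan` turns that
morphological cue into a fixed-size numerical signature: each slice of a
segmented nodule is scanned radially about its centroid, producing a
series of pole-to-boundary distances; stacking the per-slice series
gives a *shape matrix* that encodes the whole nodule's border geometry.
The shape matrix and the grayscale subvolume are then classified jointly
by a U-shaped convolutional network built from a generalized
four-dimensional convolution.

## From CT volume to shape matrix

1. **Windowing.** Hounsfield units are mapped to grayscale with the
   standard lung window (width 1600 HU, level -600 HU): everything at or
   below -1400 HU becomes 0, everything at or above 200 HU becomes 255,
   linear in between. Output stays real-valued; integer quantization
   happens only on export, to avoid double rounding in the series
   pipeline.
2. **Binarization and ROI extraction.** Slices are thresholded (Otsu's
   threshold over the whole nodule box by default — the gray histogram
   of a windowed lung box is strongly bimodal, so the parameter-free
   choice is reliable) and 8-connected components of at least `min_area`
   pixels (default 9, about a 3 mm speckle floor at 1 mm spacing) are
   kept as regions of interest, largest first. The scan pole is the
   unweighted centroid of the binary region.
3. **Boundary tracing.** The ROI's outer contour is traced with
   Moore-neighbor tracing (holes ignored, orientation normalized to
   positive signed area in the image frame). Tracing the binary region
   directly guarantees a closed simple curve; a Canny edge detector
   (`canny_edges()`, the standard four stages with configurable sigma
   and hysteresis fractions) is available as an alternative edge source,
   but its output requires edge linking and is not the default.
4. **Simplification.** The closed curve is simplified with
   Douglas-Peucker. A closed curve needs two anchors: the vertex
   farthest from the centroid starts the split (a Sato-style heuristic),
   and the index-antipodal vertex — half the cyclic vertex count away —
   is the second anchor. The two arcs are simplified independently and
   re-joined. The index-antipodal choice is O(1) and deterministic;
   picking the geometrically farthest vertex instead is available via
   configuration. All farthest-vertex selections break ties toward the
   lowest index, so results are reproducible bit for bit. The default
   tolerance is 0.8 px: below one pixel, so staircase artifacts of the
   raster boundary are removed without moving the curve by a visible
   amount.
5. **Radial scan.** Rays are cast from the pole at `360/n_angles`
   increments, counter-clockwise from the +column axis. Intersections
   with the polygon's edges are computed by exact segment-parametric
   arithmetic (no rasterization bias); when a ray crosses the boundary
   more than once — spiculated regions need not be star-shaped — the
   *farthest* intersection is taken, capturing the nodule's outer
   extent (nearest-intersection mode exists). Rays that miss entirely
   (pole outside the curve) record 0 and raise one warning.
6. **Shape matrix.** Row *k* of the matrix is slice *k*'s series; empty
   slices contribute zero rows. The default normalization divides the
   whole matrix by its maximum (`per_nodule_max`), mapping it to [0, 1]
   while preserving inter-slice size relationships, which per-slice
   normalization would destroy. Per-slice and no-op modes are available;
   normalization scope (per series / per matrix / dataset-global) is a
   genuinely open choice and is therefore configurable.

With the default 32-slice box and 32 angles (11.25° increments) the
matrix is 32x32, matching the box geometry. A 2° scan yields 180
samples per slice (`count_angles(2)`), the classic demonstration
resolution; 5.625° yields 64. The package defaults to `n_angles = 32`
so that the matrix side equals the box side — the two conventions in
circulation (5.625° increments vs a 32x32 matrix) are arithmetically
incompatible, and the square-matrix reading is the one the rest of the
pipeline depends on; the other remains one configuration flag away.

## The joint 4D input

Each sample fuses the grayscale box (rescaled to [0, 1]) with its shape
matrix into a single-channel rank-5 tensor whose fourth axis has extent
2: plane 1 is the volume, plane 2 broadcasts slice *k*'s series across
the rows of slice *k*. The embedding is deterministic and plane 1 is
exactly invertible. How volume and boundary series should be fused is
not dictated by the method itself; the broadcast-plane design was chosen
because it keeps both modalities on a common lattice so one convolution
can correlate them, and it is recorded here as a design choice.

## The generalized convolution and the network

`conv2d_ref()` and `conv4d_ref()` are literal, slow reference
implementations of the underlying convolution formulas: valid
cross-correlation with channel contributions summed, a scalar bias and
an activation. The two historical formulations differ in bias sign (the
2D form subtracts, the 4D form adds); both functions expose a
`bias_sign` switch and default to their respective conventions, with
addition used uniformly inside the network. The training path
(`conv4d()`, `cpp_conv4d_forward_train()`) is an im2col/GEMM
formulation running on BLAS, in single precision inside the training
loop; it is checked against the references in the test suite on random
tensors.

`build_unet()` assembles: an encoder of `depth` levels (two
convolutions then 2x max-pooling of the three spatial axes; filters
double per level from `base_filters`), a two-convolution bottleneck, a
decoder with nearest-neighbor upsampling and skip concatenation, and a
1-extent convolution head whose output is globally averaged into C
logits followed by softmax. Spatial kernels are 3 with same-padding;
the first convolution spans the full extent-2 plane axis (fusing the
two modalities), after which that axis has extent 1 and is never
pooled. Classification is per nodule: every reported metric is
nodule-level, so the default head is global-average + softmax; dense
per-voxel output is out of scope.

Training minimizes softmax cross-entropy with minibatch Adam. Defaults:
learning rate 5e-4, batch size 4, seeded He initialization. Two
numerical choices matter at small sample sizes:

* **Data-dependent initialization** (`calibrate_unet()`): each layer's
  weights and bias are rescaled once so every channel's pre-activation
  has roughly zero mean and unit variance over a small calibration
  batch. The correction is folded into the parameters as constants.
  Per-sample normalization layers were deliberately *not* used: they
  normalize away each sample's activation amplitude, which here carries
  the class signal (spiculation energy), whereas a constant
  recalibration preserves inter-sample contrasts.
* **Learning rate.** With a global-average head and balanced classes
  the cross-entropy has a strong saddle at uniform prediction
  (constant logits give near-zero gradients). Aggressive learning
  rates push small networks into that saddle and leave them there;
  5e-4 escapes it reliably in our experiments, and the training
  history (`model$history`) makes a collapse visible as a loss pinned
  at ln 2.

## Class balancing and evaluation

Cross-validation is stratified: within each class, shuffled members are
dealt round-robin to folds, so per-fold class counts deviate from exact
proportionality by at most one sample. Inside each training fold —
never the test fold — SMOTE brings the minority class to exact parity:
each synthetic sample is a uniform convex combination of a minority
point and one of its `k = 5` nearest minority neighbors. Interpolation
happens in the flattened joint-tensor space, the only representation
every sample shares; this is a design choice worth knowing about when
interpreting synthetic samples. With the archive's printed training
composition (550 benign / 252 malignant) parity generation means
exactly 298 synthetic samples per fold. Pooled metrics aggregate raw
test-fold contingency counts rather than averaging per-fold rates,
which is unbiased under unequal fold sizes; recall, precision, accuracy
and F1 follow the standard contingency formulas, with zero denominators
reporting 0 under a warning. A rank-based AUC of the malignant
probability is included as a convenience.

## The synthetic nodule generator

Phantom nodules are star-shaped solids: per-slice boundary radius
`r(theta, z) = R(z) (1 + a g(theta))` with `R(z)` an ellipsoidal
profile along the slice axis and `g` a unit-bounded sum of
random-phase angular harmonics. The class amplitude `a` is the
spiculation fraction — 0.05 for benign-like, 0.35 for malignant-like —
and interior/exterior gray levels (about 200 vs 40, additive noise SD
15, clipped to [0, 255]) mimic soft-tissue vs parenchyma contrast after
lung windowing. Star-shapedness makes the radial scan well-posed by
construction, so the classifier's signal is controlled.

Two geometry defaults are resolution-driven. The base radius spans
26-32% of the box edge, and harmonics use orders 3-5: boundary detail
narrower than one pixel cannot survive binarization and tracing, so
lobe wavelengths must stay above the pixel pitch for the morphology
distinction to exist at all in the rasterized mask. With these defaults
the benign/malignant separation is clearly present in the shape matrix
at a 16-voxel box, the size used by the desk-scale experiments below.

What the generator does *not* emulate: pleural attachment, vessel
touching, partial-volume effects, anisotropic spacing, or the intensity
heterogeneity of real nodules. Passing the desk-scale learning check
therefore shows that the pipeline extracts and the classifier exploits
boundary-roughness signal under controlled conditions — not that
archive-scale clinical accuracy is reproduced.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic
data: 16-voxel boxes with 16 scan angles, 50 nodules per class,
two-fold stratified cross-validation, depth-2 networks with 4 or 8 base
filters trained 25 epochs, repeated over three seeds. These sizes keep
a full dual-model, multi-seed comparison in the minutes range on a
single CPU while preserving every structural property of the full-size
configuration (32-cube boxes, depth 3-4, 10 folds), which remains the
package default for real use.

## Known limitations

* The Canny edge source is the standard four-stage detector; the
  "modified" variants cited in parts of the literature are not
  specified precisely enough to reproduce, so the modification is not
  implemented.
* Whether simplification should feed the radial scan or only auxiliary
  feature extraction is ambiguous in the source material; here it
  optionally smooths the curve before scanning (default on).
* DICOM input is not supported (no DICOM reader in the supported
  dependency set); NIfTI, PNG/TIFF mask stacks and a plain-text array
  container are.
* Training is CPU-bound R/C++ with single-precision GEMMs; it is meant
  for desk-scale experiments, not archive-scale training runs.
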