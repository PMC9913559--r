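# radscan

Radial-scanning shape signatures and 4D convolutional classification of
lung nodules in CT.

Malignant pulmonary nodules tend to have spiculated, irregular borders;
benign ones are usually smooth. `radscan` encodes that cue numerically:
each slice of a segmented nodule box is binarized, its outer boundary is
traced and simplified (closed-curve Douglas–Peucker), and the distance
from the region centroid to the boundary is sampled at regular angular
increments,

```
r_k = distance from centroid to the farthest boundary intersection
      along the ray at angle theta_k = k * 360 / n_angles,   k = 0 .. n_angles - 1.
```

Stacking the per-slice series gives the **shape matrix** `S[z, k]`
(slices x angles; 32 x 32 at the defaults), a fixed-size signature of
the nodule's border geometry. The shape matrix and the grayscale
subvolume are fused into a single rank-5 tensor (an extent-2 "plane"
axis carrying volume and broadcast shape matrix) and classified
benign/malignant by a U-shaped encoder–decoder built from a generalized
4D convolution

```
y[k,l,m,n] = phi( sum_c sum_r sum_d sum_i sum_j
                  w[c,r,d,i,j] * x[c, k+r, l+d, m+i, n+j] + b ),
```

trained with softmax cross-entropy. The evaluation protocol is
stratified k-fold cross-validation with SMOTE minority oversampling
applied inside each training fold only, and contingency-table metrics
(recall, precision, accuracy, F1).

The package is aimed at researchers experimenting with boundary-series
representations of volumetric lesions: every stage (windowing, ROI
extraction, tracing, simplification, scanning, classification,
balancing, evaluation) is exposed as a documented function, and a
synthetic nodule generator with controllable spiculation makes the whole
pipeline runnable without any imaging archive.

## Worked example

Generate a small synthetic two-class dataset, build the shape matrices,
and cross-validate a depth-2 classifier:

```r
library(radscan)

ds      <- gen_dataset(synth_config(box_size = 16, n_per_class = 20, seed = 7))
samples <- prepare_samples(ds$boxes)            # binarize -> trace -> simplify -> scan -> fuse
plan    <- make_folds(ds$manifest$label, n_folds = 2, seed = 7)
cfg     <- unet_config(depth = 2, base_filters = 4, epochs = 25, seed = 7)
res     <- cross_validate(samples, cfg, plan)
res$pooled
#> recall 0.9000  precision 0.8571  accuracy 0.8750  F1 0.8780
res$auc
#> [1] 0.945
```

`recall` is the fraction of malignant nodules caught, `precision` the
fraction of malignant calls that were right, `accuracy` the overall hit
rate pooled over the held-out folds, and `auc` ranks the malignant
probability. With 20 nodules per class this runs in about a minute on
one CPU; the per-fold reports are in `res$per_fold`, and SMOTE activity
per fold in `res$n_synthetic` (zero here, the classes being balanced).

A single nodule's signature:

```r
box <- gen_nodule_volume(synth_config(box_size = 16), "malignant", seed = 1)
sm  <- nodule_shape_matrix(box)     # 16 x 16, rows = slices, in [0, 1]
round(sm[8, ], 2)                   # equatorial slice's radial series
#>  [1] 1.00 0.69 0.60 0.71 0.91 0.92 0.80 0.81 0.84 0.73 0.75 0.90 0.90 0.77 0.71 0.77
```

The ragged series is the spiculation; a benign-like nodule
(`amplitude 0.05`) gives a nearly constant row.

A thin command-line front-end is installed with the package
(`system.file("cli", "radscan", package = "radscan")`) with subcommands
`window`, `boundary`, `series`, `synth`, `cv`, `run`.

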