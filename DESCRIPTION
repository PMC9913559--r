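Package: radscan
Title: Radial-Scanning Shape Signatures and 4D Convolutional
    Classification of Lung Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts segmented lung-nodule CT volumes into
    boundary-distance series by radial scanning: each slice's region of
    interest is binarized, its closed boundary curve is traced and
    simplified with a closed-curve Douglas-Peucker procedure, and the
    distance from the region centroid to the boundary is sampled at
    regular angular increments. Per-slice series are stacked into a
    slices-by-angles shape matrix that encodes the nodule's border
    geometry. A U-shaped encoder-decoder network built from a
    generalized four-dimensional convolution classifies the joint
    (gray volume, shape matrix) input as benign or malignant, with
    SMOTE minority oversampling inside stratified cross-validation
    folds and standard contingency-table metrics. A synthetic nodule
    generator with controllable spiculation makes the full pipeline
    testable without any imaging archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    Rcpp,
    png,
    stats,
    tiff,
    tools,
    utils,
    xml2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
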