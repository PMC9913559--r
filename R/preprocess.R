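#' CT volume container
#'
#' A 3D stack of Hounsfield-unit voxels in (slice, row, column) order
#' together with the voxel spacing in mm.
#'
#' @param voxels numeric 3D array of Hounsfield units.
#' @param spacing numeric length-3 vector `(z, y, x)` in mm, all > 0.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L) stopf("voxels must be a 3D array")
  if (dim(voxels)[1L] < 1L) stopf("volume needs at least one slice")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be three positive numbers (z, y, x)")
  structure(list(voxels = voxels, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d slices x %d x %d, spacing %.3g/%.3g/%.3g mm\n",
              d[1L], d[2L], d[3L], x$spacing[1L], x$spacing[2L], x$spacing[3L]))
  invisible(x)
}

#' CT display window
#'
#' Window width and level in Hounsfield units. The default (width 1600,
#' level -600) is the standard lung window used to normalize contrast
#' before binarization.
#'
#' @param width window width in HU, > 0.
#' @param level window center in HU.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(width = 1600, level = -600) {
  if (!is.finite(width) || width <= 0) stopf("window width must be > 0")
  structure(list(width = as.numeric(width), level = as.numeric(level)),
            class = "window_spec")
}

#' Map Hounsfield units to grayscale
#'
#' Linear window/level mapping: values at or below `level - width/2`
#' become 0, values at or above `level + width/2` become 255, with a
#' linear ramp in between. Output stays real-valued; quantization to
#' integers happens only on export.
#'
#' @param volume a [ct_volume()] or a numeric array of HU values.
#' @param spec a [window_spec()].
#' @return numeric array of the same shape with values in `[0, 255]`.
#' @export
window_hu <- function(volume, spec = window_spec()) {
  hu <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  bad <- which(!is.finite(hu))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(hu) %||% length(hu))
    stopf("non-finite HU value at voxel (%s)", paste(idx - 1L, collapse = ", "))
  }
  lo <- spec$level - spec$width / 2
  g <- (hu - lo) / spec$width
  g[g < 0] <- 0
  g[g > 1] <- 1
  g * 255
}

#' Threshold a grayscale slice
#'
#' @param gray_slice numeric 2D array.
#' @param threshold scalar; a pixel is foreground iff its value is
#'   greater than or equal to the threshold.
#' @return logical matrix.
#' @export
binarize <- function(gray_slice, threshold) {
  if (!is.finite(threshold)) stopf("threshold must be finite")
  gray_slice >= threshold
}

#' Otsu threshold of a grayscale image
#'
#' Default binarization threshold for windowed lung slices; wraps the
#' classic histogram criterion for values in `[0, 255]`.
#'
#' @param gray numeric array with values in `[0, 255]`.
#' @return scalar threshold on the 0-255 scale.
#' @export
otsu_threshold <- function(gray) {
  EBImage::otsu(EBImage::Image(as.vector(gray) / 255), range = c(0, 1),
                levels = 256L) * 255
}

#' Region-of-interest mask
#'
#' @param pixels logical matrix with at least one `TRUE` pixel.
#' @param slice_index 0-based slice index the mask belongs to.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(pixels, slice_index = 0L) {
  if (!is.matrix(pixels)) stopf("pixels must be a matrix")
  pixels <- pixels & TRUE
  if (!any(pixels)) stopf("an ROI needs at least one true pixel")
  structure(list(pixels = pixels, slice_index = as.integer(slice_index)),
            class = "roi_mask")
}

# 8-connected labelling: EBImage's bwlabel is 4-connected, so labels that
# touch diagonally are merged afterwards with a small union-find
label_components <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (connectivity == 8L && n > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),
      cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L])))
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(n), find, integer(1L))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  lab
}

#' Extract regions of interest from a binary mask
#'
#' Finds the 8-connected components of the foreground, discards those
#' smaller than `min_area` pixels, and returns the survivors ordered by
#' decreasing area.
#'
#' @param mask logical matrix.
#' @param min_area minimum component area in pixels (default 9, about a
#'   3-pixel diameter: speckle smaller than the 3 mm nodule floor at
#'   ~1 mm spacing).
#' @param slice_index 0-based slice index recorded on each ROI.
#' @param connectivity 4 or 8 (default 8).
#' @return list of [roi_mask()] objects (possibly empty).
#' @export
extract_rois <- function(mask, min_area = 9L, slice_index = 0L,
                         connectivity = 8L) {
  if (min_area < 1L) stopf("min_area must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  mask <- mask & TRUE
  if (!any(mask)) return(list())
  lab <- label_components(mask, connectivity)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  lapply(keep, function(k) roi_mask(lab == k, slice_index))
}

#' Unweighted centroid of an ROI
#'
#' Mean of the true-pixel coordinates under the 0-based, pixel-center
#' convention: the binary mask needs no intensity weighting.
#'
#' @param roi an [roi_mask()] or logical matrix.
#' @return numeric `(row, col)`.
#' @export
roi_centroid <- function(roi) {
  px <- if (inherits(roi, "roi_mask")) roi$pixels else roi & TRUE
  if (!any(px)) stopf("cannot take the centroid of an empty ROI")
  ij <- which(px, arr.ind = TRUE) - 1L
  c(row = mean(ij[, 1L]), col = mean(ij[, 2L]))
}

#' Fixed-size nodule box
#'
#' The unit of classification: a size-cubed grayscale subvolume centered
#' on a nodule, with spacing, class label and the source-volume center it
#' was cut from.
#'
#' @param gray numeric 3D array with values in `[0, 255]`.
#' @param spacing `(z, y, x)` voxel spacing in mm.
#' @param label `"benign"`, `"malignant"`, or `NA`.
#' @param center_voxel 0-based `(z, y, x)` integer center in the source
#'   volume.
#' @param padding 3x2 matrix of zero-padded voxel counts (low, high) per
#'   axis, as recorded by [crop_box()].
#' @return an object of class `nodule_box`.
#' @export
nodule_box <- function(gray, spacing = c(1, 1, 1), label = NA_character_,
                       center_voxel = c(0L, 0L, 0L),
                       padding = matrix(0L, 3L, 2L)) {
  if (length(dim(gray)) != 3L) stopf("gray must be a 3D array")
  if (length(unique(dim(gray))) != 1L)
    stopf("box edges must all have the configured size")
  rng <- range(gray)
  if (rng[1L] < 0 || rng[2L] > 255) stopf("gray values must lie in [0, 255]")
  if (!is.na(label) && !label %in% c("benign", "malignant"))
    stopf("label must be 'benign' or 'malignant'")
  structure(list(gray = gray, spacing = as.numeric(spacing), label = label,
                 center_voxel = as.integer(center_voxel), padding = padding),
            class = "nodule_box")
}

#' @export
print.nodule_box <- function(x, ...) {
  cat(sprintf("<nodule_box> %s, %s, center (%s)\n",
              paste(dim(x$gray), collapse = "x"),
              if (is.na(x$label)) "unlabelled" else x$label,
              paste(x$center_voxel, collapse = ", ")))
  invisible(x)
}

#' Crop a fixed-size box around a voxel
#'
#' Cuts a `size`-cubed box from a grayscale volume using the
#' floor-centered, half-open convention: each axis spans
#' `[c - floor(size/2), c - floor(size/2) + size)`. Regions falling
#' outside the volume are zero-padded and the padding is recorded.
#'
#' @param volume_gray numeric 3D array in `[0, 255]`, (z, y, x) order.
#' @param center 0-based integer `(z, y, x)` center; must lie inside the
#'   volume.
#' @param size box edge length, >= 2.
#' @param spacing,label passed through to [nodule_box()].
#' @return a [nodule_box()].
#' @export
crop_box <- function(volume_gray, center, size = 32L,
                     spacing = c(1, 1, 1), label = NA_character_) {
  if (size < 2L) stopf("size must be >= 2")
  d <- dim(volume_gray)
  center <- as.integer(round(center))
  if (any(center < 0L) || any(center >= d))
    stopf("center (%s) lies outside the volume", paste(center, collapse = ", "))
  start <- center - size %/% 2L                 # 0-based, inclusive
  box <- array(0, rep(size, 3L))
  pad <- matrix(0L, 3L, 2L, dimnames = list(c("z", "y", "x"), c("low", "high")))
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    lo <- max(start[a], 0L)
    hi <- min(start[a] + size - 1L, d[a] - 1L)
    pad[a, ] <- c(lo - start[a], start[a] + size - 1L - hi)
    src[[a]] <- (lo:hi) + 1L
    dst[[a]] <- (lo:hi) - start[a] + 1L
  }
  box[dst[[1L]], dst[[2L]], dst[[3L]]] <-
    volume_gray[src[[1L]], src[[2L]], src[[3L]]]
  nodule_box(box, spacing, label, center, pad)
}

#' Re-embed a box into a volume-sized array (inverse of the crop)
#' @param box a [nodule_box()].
#' @param volume_dim integer dims of the target volume.
#' @return numeric array of size `volume_dim`, zero outside the box.
#' @export
embed_box <- function(box, volume_dim) {
  size <- dim(box$gray)[1L]
  start <- box$center_voxel - size %/% 2L
  out <- array(0, volume_dim)
  for (a in 1:3) {
    lo <- max(start[a], 0L); hi <- min(start[a] + size - 1L, volume_dim[a] - 1L)
    if (lo > hi) stopf("box does not overlap the volume on axis %d", a)
  }
  idx <- lapply(1:3, function(a) {
    lo <- max(start[a], 0L); hi <- min(start[a] + size - 1L, volume_dim[a] - 1L)
    list(src = (lo:hi) - start[a] + 1L, dst = (lo:hi) + 1L)
  })
  out[idx[[1L]]$dst, idx[[2L]]$dst, idx[[3L]]$dst] <-
    box$gray[idx[[1L]]$src, idx[[2L]]$src, idx[[3L]]$src]
  out
}

#' Apply the nodule inclusion filters
#'
#' Retains annotations with diameter between 3 and 30 mm, malignancy
#' grade other than 3 (the indeterminate middle grade is dropped), and
#' solid morphology; grades 1-2 are labelled benign and 4-5 malignant.
#'
#' @param annotations data frame with columns `diameter_mm`,
#'   `malignancy` (integer 1-5) and `solid` (logical), e.g. from
#'   [read_annotations()].
#' @return the retained rows with an added `label` column.
#' @export
filter_nodules <- function(annotations) {
  need <- c("diameter_mm", "malignancy", "solid")
  if (!all(need %in% names(annotations)))
    stopf("annotations must have columns %s", paste(need, collapse = ", "))
  g <- annotations$malignancy
  if (any(!g %in% 1:5))
    stopf("malignancy grade outside 1..5: %s",
          paste(unique(g[!g %in% 1:5]), collapse = ", "))
  keep <- annotations$diameter_mm >= 3 & annotations$diameter_mm <= 30 &
    g != 3L & annotations$solid
  out <- annotations[keep, , drop = FALSE]
  out$label <- ifelse(out$malignancy <= 2L, "benign", "malignant")
  rownames(out) <- NULL
  out
}
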