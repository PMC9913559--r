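#' Radial-scan settings
#'
#' A full-circle scan at `n_angles` regular increments; the increment is
#' always `360 / n_angles` degrees. The default of 32 angles pairs with
#' the default 32-slice box so the stacked shape matrix is 32x32.
#'
#' @param n_angles number of scan angles, >= 4.
#' @param normalize `"per_nodule_max"` (default: divide the whole shape
#'   matrix by its maximum, preserving inter-slice size relationships),
#'   `"per_slice_max"`, or `"none"`.
#' @param intersection `"farthest"` (default: the outer extent of
#'   spiculated, non-star-shaped boundaries) or `"nearest"`.
#' @return an object of class `radial_config`.
#' @export
radial_config <- function(n_angles = 32L,
                          normalize = c("per_nodule_max", "per_slice_max", "none"),
                          intersection = c("farthest", "nearest")) {
  n_angles <- as.integer(n_angles)
  if (n_angles < 4L) stopf("n_angles must be >= 4")
  structure(list(n_angles = n_angles,
                 angle_increment = 360 / n_angles,
                 normalize = match.arg(normalize),
                 intersection = match.arg(intersection)),
            class = "radial_config")
}

#' Number of scan angles for an angular increment
#'
#' @param angle_increment increment in degrees; must divide 360.
#' @return integer `360 / angle_increment`.
#' @examples
#' count_angles(2)      # 180 samples per slice
#' count_angles(11.25)  # 32
#' @export
count_angles <- function(angle_increment) {
  n <- 360 / angle_increment
  if (abs(n - round(n)) > 1e-9)
    stopf("%g degrees does not divide the full circle", angle_increment)
  as.integer(round(n))
}

#' Radial distance series of a boundary curve
#'
#' Casts a ray from the pole at each angle `theta_k = k * 360/n_angles`
#' degrees (k = 0..n_angles-1, measured counter-clockwise from the
#' +column axis in the image frame) and records the distance to the
#' farthest intersection with the polygon's edges (exact
#' segment-parametric arithmetic, Euclidean pixel units). Rays that miss
#' the polygon entirely - the pole outside or on the curve - contribute
#' 0 and raise one warning.
#'
#' @param curve a [boundary_curve()].
#' @param pole numeric `(row, col)` scan center, normally the ROI
#'   centroid.
#' @param cfg a [radial_config()].
#' @return an object of class `radial_series` with fields `values`
#'   (length `n_angles`, >= 0), `pole`, `slice_index` and
#'   `angles_deg`.
#' @export
radial_series <- function(curve, pole, cfg = radial_config()) {
  pts <- curve$points
  n <- nrow(pts)
  if (n < 3L) stopf("degenerate curve: fewer than 3 points")
  p1 <- pts
  p2 <- pts[c(2:n, 1L), , drop = FALSE]
  if (!point_in_polygon(pole, p1, p2)) {
    warnf("ray(s) with no boundary intersection (pole outside or on the curve); zeros recorded")
    return(structure(list(values = numeric(cfg$n_angles),
                          pole = as.numeric(pole),
                          slice_index = curve$slice_index,
                          angles_deg = (seq_len(cfg$n_angles) - 1L) *
                            cfg$angle_increment),
                     class = "radial_series"))
  }
  ex <- p2[, 2L] - p1[, 2L]   # x = col
  ey <- p2[, 1L] - p1[, 1L]   # y = row
  qx <- p1[, 2L] - pole[2L]
  qy <- p1[, 1L] - pole[1L]
  theta <- (seq_len(cfg$n_angles) - 1L) * 2 * pi / cfg$n_angles
  vals <- numeric(cfg$n_angles)
  missed <- FALSE
  for (k in seq_along(theta)) {
    dx <- cos(theta[k]); dy <- sin(theta[k])
    den <- dx * ey - dy * ex            # cross(dir, edge)
    ok <- abs(den) > 1e-12
    t <- (qx * ey - qy * ex) / den      # along the ray
    s <- (qx * dy - qy * dx) / den      # along the edge
    hit <- ok & s >= -1e-12 & s < 1 - 1e-12 & t > 1e-12
    if (any(hit)) {
      vals[k] <- if (cfg$intersection == "farthest") max(t[hit]) else min(t[hit])
    } else missed <- TRUE
  }
  if (missed)
    warnf("ray(s) with no boundary intersection (pole outside or on the curve); zeros recorded")
  structure(list(values = vals, pole = as.numeric(pole),
                 slice_index = curve$slice_index,
                 angles_deg = theta * 180 / pi),
            class = "radial_series")
}

# even-odd rule with a horizontal ray in the (x = col, y = row) frame
point_in_polygon <- function(p, p1, p2) {
  y1 <- p1[, 1L]; y2 <- p2[, 1L]
  x1 <- p1[, 2L]; x2 <- p2[, 2L]
  straddle <- (y1 > p[1L]) != (y2 > p[1L])
  if (!any(straddle)) return(FALSE)
  xi <- x1[straddle] + (p[1L] - y1[straddle]) /
    (y2[straddle] - y1[straddle]) * (x2[straddle] - x1[straddle])
  sum(xi > p[2L]) %% 2L == 1L
}

#' Stack per-slice radial series into the shape matrix
#'
#' Row k of the shape matrix is the radial series of slice k of the
#' nodule box; slices without an ROI give zero rows. With the default
#' `per_nodule_max` normalization the whole matrix is divided by its
#' maximum, so the largest distance anywhere in the box maps to 1 and
#' relative slice sizes are preserved (an empty box stays all-zero, with
#' a warning).
#'
#' @param box_curves list of length `n_slices`; element k is the
#'   [boundary_curve()] of slice k-1, or `NULL` where the slice has no
#'   ROI.
#' @param poles numeric `n_slices x 2` matrix of per-slice `(row, col)`
#'   poles (rows ignored for `NULL` slices).
#' @param cfg a [radial_config()].
#' @return a `slices x n_angles` matrix of class `shape_matrix`.
#' @export
build_shape_matrix <- function(box_curves, poles, cfg = radial_config()) {
  n_slices <- length(box_curves)
  poles <- matrix(poles, ncol = 2L)
  m <- matrix(0, n_slices, cfg$n_angles)
  for (k in seq_len(n_slices)) {
    if (is.null(box_curves[[k]])) next
    m[k, ] <- radial_series(box_curves[[k]], poles[k, ], cfg)$values
  }
  if (all(m == 0)) {
    warnf("all slices empty: shape matrix is all-zero")
  } else if (cfg$normalize == "per_nodule_max") {
    m <- m / max(m)
  } else if (cfg$normalize == "per_slice_max") {
    mx <- apply(m, 1L, max)
    nz <- mx > 0
    m[nz, ] <- m[nz, , drop = FALSE] / mx[nz]
  }
  structure(m, class = c("shape_matrix", "matrix"),
            normalize = cfg$normalize)
}

#' Shape matrix of a nodule box
#'
#' Runs the per-slice stages end to end on one box: binarize (Otsu
#' threshold over the whole box unless given), keep the largest ROI of
#' each slice, trace its boundary, optionally simplify it with the
#' closed-curve Douglas-Peucker procedure, and radially scan it about
#' its centroid. Slices with no usable ROI (nothing above threshold, or
#' a region too thin to bound area) become zero rows.
#'
#' @param box a [nodule_box()].
#' @param cfg a [radial_config()]; by default the angle count equals the
#'   box's slice count, so the matrix stacks square.
#' @param threshold binarization threshold on the 0-255 scale; default
#'   is Otsu's threshold computed over the whole box.
#' @param min_area minimum ROI area in pixels.
#' @param simplify simplify each boundary before scanning (default TRUE).
#' @param epsilon Douglas-Peucker tolerance in pixels.
#' @return a [build_shape_matrix()] result.
#' @export
nodule_shape_matrix <- function(box, cfg = NULL,
                                threshold = NULL, min_area = 9L,
                                simplify = TRUE, epsilon = 0.8) {
  gray <- box$gray
  n_slices <- dim(gray)[1L]
  if (is.null(cfg)) cfg <- radial_config(n_angles = n_slices)
  if (is.null(threshold)) threshold <- otsu_threshold(gray)
  curves <- vector("list", n_slices)
  poles <- matrix(0, n_slices, 2L)
  for (k in seq_len(n_slices)) {
    mask <- binarize(gray[k, , ], threshold)
    rois <- extract_rois(mask, min_area = min_area, slice_index = k - 1L)
    if (!length(rois)) next
    roi <- rois[[1L]]
    cv <- tryCatch(trace_boundary(roi), error = function(e) NULL)
    if (is.null(cv)) next
    ctr <- roi_centroid(roi)
    if (simplify && nrow(cv$points) > 4L)
      cv <- dp_simplify_closed(cv, epsilon, ctr)
    curves[[k]] <- cv
    poles[k, ] <- ctr
  }
  suppressWarnings(build_shape_matrix(curves, poles, cfg))
}
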