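#' Canny edge-detector settings
#'
#' @param gaussian_sigma smoothing scale in pixels, > 0.
#' @param low_threshold,high_threshold hysteresis thresholds as fractions
#'   of the maximum gradient magnitude, `0 < low < high <= 1`.
#' @return an object of class `canny_config`.
#' @export
canny_config <- function(gaussian_sigma = 1.0, low_threshold = 0.1,
                         high_threshold = 0.2) {
  if (gaussian_sigma <= 0) stopf("gaussian_sigma must be > 0")
  if (!(low_threshold > 0 && low_threshold < high_threshold &&
        high_threshold <= 1))
    stopf("need 0 < low_threshold < high_threshold <= 1")
  structure(list(gaussian_sigma = gaussian_sigma,
                 low_threshold = low_threshold,
                 high_threshold = high_threshold), class = "canny_config")
}

#' Canny edge map of a grayscale slice
#'
#' The standard four stages: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' hysteresis thresholding (weak edges survive only in components that
#' contain a strong edge). A constant image yields an empty map.
#'
#' @param gray_slice numeric matrix, at least 3x3.
#' @param cfg a [canny_config()].
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(gray_slice, cfg = canny_config()) {
  if (nrow(gray_slice) < 3L || ncol(gray_slice) < 3L)
    stopf("slice must be at least 3x3")
  sz <- 2L * ceiling(3 * cfg$gaussian_sigma) + 1L
  brush <- EBImage::makeBrush(sz, shape = "gaussian",
                              sigma = cfg$gaussian_sigma)
  sm <- EBImage::filter2(gray_slice, brush, boundary = "replicate")
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L)
  gr <- EBImage::filter2(sm, kx, boundary = "replicate")        # d/drow
  gc <- EBImage::filter2(sm, t(kx), boundary = "replicate")     # d/dcol
  mag <- sqrt(gr^2 + gc^2)
  mx <- max(mag)
  if (mx <= .Machine$double.eps) return(matrix(FALSE, nrow(gray_slice), ncol(gray_slice)))
  ang <- atan2(gr, gc)
  sector <- (round(ang / (pi / 4)) %% 4L)  # 0: col, 1: diag, 2: row, 3: anti-diag
  nr <- nrow(mag); nc <- ncol(mag)
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  shift <- function(m, dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  nms <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    d <- off[[s + 1L]]
    fwd <- shift(mag, d[1L], d[2L])
    bwd <- shift(mag, -d[1L], -d[2L])
    nms <- nms | (sector == s & mag >= fwd & mag > bwd)
  }
  nms[c(1L, nr), ] <- FALSE
  nms[, c(1L, nc)] <- FALSE
  strong <- nms & mag >= cfg$high_threshold * mx
  weak <- nms & mag >= cfg$low_threshold * mx
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lab <- label_components(weak, 8L)
  keep <- unique(lab[strong])
  weak & matrix(lab %in% keep, nr, nc)
}

#' Closed boundary curve of one slice's ROI
#'
#' @param points numeric n x 2 matrix of `(row, col)` vertices, n >= 3,
#'   consecutive vertices distinct; the polygon is implicitly closed.
#' @param slice_index 0-based slice index.
#' @return an object of class `boundary_curve`.
#' @export
boundary_curve <- function(points, slice_index = 0L) {
  points <- matrix(as.numeric(points), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(points) < 3L) stopf("a boundary curve needs at least 3 points")
  dup <- rowSums(abs(points - points[c(2:nrow(points), 1L), ])) == 0
  if (any(dup[-length(dup)])) stopf("consecutive curve points must be distinct")
  if (dup[length(dup)]) points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) < 3L) stopf("a boundary curve needs at least 3 points")
  structure(list(points = points, slice_index = as.integer(slice_index)),
            class = "boundary_curve")
}

# signed polygon area with x = col, y = row; positive = counter-clockwise
# in the package's image frame
signed_area <- function(pts) {
  x <- pts[, 2L]; y <- pts[, 1L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Trace the outer contour of an ROI
#'
#' Moore-neighbor tracing of the region's outer boundary pixels,
#' returned as a closed curve oriented counter-clockwise in the image
#' frame (positive signed area with x = column, y = row). Interior holes
#' are ignored. Regions too thin to bound any area (single rows/columns,
#' < 3 boundary pixels) are degenerate and raise an error.
#'
#' @param roi an [roi_mask()] or logical matrix containing one connected
#'   component.
#' @return a [boundary_curve()] whose vertices are boundary pixel
#'   centers, 0-based `(row, col)`.
#' @export
trace_boundary <- function(roi) {
  slice_index <- if (inherits(roi, "roi_mask")) roi$slice_index else 0L
  px <- if (inherits(roi, "roi_mask")) roi$pixels else roi & TRUE
  if (sum(px) < 3L) stopf("degenerate ROI: fewer than 3 boundary pixels")
  nr <- nrow(px); nc <- ncol(px)
  P <- matrix(FALSE, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- px
  # uppermost-leftmost foreground pixel (row-major scan)
  ij <- which(P, arr.ind = TRUE)
  start <- ij[order(ij[, 1L], ij[, 2L])[1L], ]
  # Moore neighborhood in clockwise scan order starting at W
  nb <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
              c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  cur <- start
  bt <- start + c(0L, -1L)  # backtrack pixel: W of start is background
  bt0 <- bt
  path <- matrix(0L, 8L * sum(px) + 8L, 2L)
  np <- 0L
  repeat {
    np <- np + 1L
    # thin out-and-back regions can cycle without re-entering the start
    # with the original backtrack; a full cycle is surely within the
    # budget, and the degeneracy checks below handle what it collected
    if (np > nrow(path)) { np <- np - 1L; break }
    path[np, ] <- cur
    rel <- bt - cur
    k <- which(nb[, 1L] == rel[1L] & nb[, 2L] == rel[2L])
    prev <- bt
    nxt <- NULL
    for (step in 1:8) {
      k <- k %% 8L + 1L
      cand <- cur + nb[k, ]
      if (P[cand[1L], cand[2L]]) { nxt <- cand; break }
      prev <- cand
    }
    if (is.null(nxt)) break  # isolated pixel; cannot occur for >= 3 connected px
    cur <- nxt
    bt <- prev
    # Jacob's criterion: second visit to the start with the same backtrack
    if (all(cur == start) && all(bt == bt0)) break
  }
  pts <- path[seq_len(np), , drop = FALSE] - 2L  # back to 0-based coords
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  upts <- unique(pts)
  if (nrow(upts) < 3L) stopf("degenerate ROI: no closed curve exists")
  if (abs(signed_area(upts)) <= .Machine$double.eps)
    stopf("degenerate ROI: boundary encloses no area")
  # out-and-back excursions along 1-px-thin spurs keep duplicated points;
  # that is fine for scanning, but orientation must be consistent
  if (signed_area(upts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  if (nrow(pts) > 1L && all(pts[1L, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  boundary_curve(pts, slice_index)
}

# distance from points (n x 2) to the segment a--b
point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 <= .Machine$double.eps) return(sqrt(rowSums(sweep(pts, 2L, a)^2)))
  t <- pmin(1, pmax(0, (sweep(pts, 2L, a) %*% ab) / len2))
  proj <- cbind(a[1L] + t * ab[1L], a[2L] + t * ab[2L])
  sqrt(rowSums((pts - proj)^2))
}

#' Douglas-Peucker simplification of an open polyline
#'
#' Top-down recursion: starting from the chord joining the endpoints,
#' the vertex farthest from the current chord (ties broken by lowest
#' index) is kept whenever it deviates by more than `tolerance`, and the
#' two sub-polylines are simplified recursively. Every input vertex ends
#' up within `tolerance` of the simplified polyline, and the output is a
#' subset of the input including both endpoints.
#'
#' @param points numeric n x 2 matrix `(row, col)`, n >= 2.
#' @param tolerance epsilon > 0, in pixels.
#' @return m x 2 matrix of retained vertices, in input order.
#' @export
dp_simplify_open <- function(points, tolerance) {
  points <- matrix(as.numeric(points), ncol = 2L)
  n <- nrow(points)
  if (n < 2L) stopf("need at least 2 points")
  if (tolerance <= 0) stopf("tolerance must be > 0")
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- point_segment_distance(points[mid, , drop = FALSE],
                                points[i, ], points[j, ])
    w <- which.max(d)          # ties: lowest index
    if (d[w] > tolerance) {
      k <- mid[w]
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k), c(k, j)))
    }
  }
  points[keep, , drop = FALSE]
}

#' Douglas-Peucker simplification of a closed boundary curve
#'
#' Splitting a closed curve needs two anchors. The first anchor is the
#' vertex farthest from the region center (ties broken by lowest index);
#' the second is the index-antipodal vertex, half the cyclic vertex
#' count away along the point sequence. The two arcs between the anchors
#' are simplified independently with [dp_simplify_open()] and
#' re-joined, so the result is closed, contains both anchors, and keeps
#' every original vertex within `tolerance` of the simplified polygon.
#'
#' @param curve a [boundary_curve()].
#' @param tolerance epsilon > 0, in pixels.
#' @param center numeric `(row, col)` region centroid used to pick the
#'   starting anchor.
#' @return a simplified [boundary_curve()].
#' @export
dp_simplify_closed <- function(curve, tolerance, center) {
  pts <- curve$points
  n <- nrow(pts)
  if (n < 3L) stopf("a closed curve needs at least 3 points")
  if (n == 3L) return(curve)
  d2 <- (pts[, 1L] - center[1L])^2 + (pts[, 2L] - center[2L])^2
  a <- which.max(d2)                       # ties: lowest index
  ord <- ((seq_len(n) + a - 2L) %% n) + 1L  # rotate so anchor A is first
  pts <- pts[ord, , drop = FALSE]
  b <- n %/% 2L + 1L                       # index-antipodal second anchor
  arc1 <- dp_simplify_open(pts[1:b, , drop = FALSE], tolerance)
  arc2 <- dp_simplify_open(pts[c(b:n, 1L), , drop = FALSE], tolerance)
  out <- rbind(arc1, arc2[-c(1L, nrow(arc2)), , drop = FALSE])
  boundary_curve(out, curve$slice_index)
}
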