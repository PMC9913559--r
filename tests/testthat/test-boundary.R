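test_that("canny_edges finds rings around disks and nothing in flat images", {
  expect_false(any(canny_edges(matrix(5, 16, 16))))

  img <- matrix(20, 41, 41)
  img[raster_disk(41, c(20, 20), 12)] <- 220
  ed <- canny_edges(img)
  expect_true(any(ed))
  rc <- which(ed, arr.ind = TRUE) - 1
  radii <- sqrt((rc[, 1] - 20)^2 + (rc[, 2] - 20)^2)
  # edge pixels hug the circumference (smoothing blurs by about sigma)
  expect_true(all(abs(radii - 12) <= 2.5))
  expect_gt(length(radii), 20)
})

test_that("canny_edges localizes a vertical step to one column pair", {
  img <- matrix(0, 21, 21)
  img[, 11:21] <- 200
  ed <- canny_edges(img)
  cols <- unique(which(ed, arr.ind = TRUE)[, 2])
  expect_true(length(cols) >= 1 && all(cols %in% 10:12))
})

test_that("trace_boundary walks the outer contour counter-clockwise", {
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  cv <- trace_boundary(m)
  expect_equal(nrow(cv$points), 8)
  # vertex set == boundary pixels of the block (all 8 perimeter pixels)
  expect_setequal(paste(cv$points[, 1], cv$points[, 2]),
                  c("1 1", "1 2", "1 3", "2 1", "2 3", "3 1", "3 2", "3 3"))
  # positive signed area in the (x = col, y = row) frame
  expect_gt(radscan:::signed_area(cv$points), 0)

  thin <- matrix(FALSE, 3, 7); thin[2, 2:6] <- TRUE
  expect_error(trace_boundary(thin), "degenerate")

  # holes are ignored: annulus traces only the outer rim
  ann <- raster_disk(31, c(15, 15), 10) & !raster_disk(31, c(15, 15), 4)
  cva <- trace_boundary(ann)
  radii <- sqrt(rowSums(sweep(cva$points, 2, c(15, 15))^2))
  expect_true(all(radii > 7))
})

test_that("trace_boundary length approximates a disk circumference", {
  m <- raster_disk(25, c(12, 12), 8)
  p <- trace_boundary(m)$points
  len <- sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), ])^2)))
  expect_lt(abs(len - 2 * pi * 8) / (2 * pi * 8), 0.10)
  # oracle: traced vertices are exactly the pixels with a 4-neighbor
  # background (the outer contour an 8-connected walk follows)
  inner <- m & EBImage::erode(m * 1, EBImage::makeBrush(3, "diamond")) > 0
  boundary_px <- which(m & !inner, arr.ind = TRUE) - 1
  expect_setequal(paste(p[, 1], p[, 2]),
                  paste(boundary_px[, 1], boundary_px[, 2]))
})

test_that("dp_simplify_open keeps endpoints and honors the tolerance", {
  line <- cbind(0:9, 2 * (0:9))                  # collinear
  expect_equal(nrow(dp_simplify_open(line, 0.1)), 2)

  kink <- rbind(c(0, 0), c(0.4, 1), c(0, 2))     # deviation 0.4
  expect_equal(nrow(dp_simplify_open(kink, 0.5)), 2)
  expect_equal(nrow(dp_simplify_open(kink, 0.3)), 3)

  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    pts <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))
    eps <- runif(1, 0.2, 3)
    simp <- dp_simplify_open(pts, eps)
    # vertices are a subset of the input, endpoints included
    expect_true(all(simp[, 1] %in% pts[, 1]))
    expect_equal(simp[1, ], pts[1, ])
    expect_equal(simp[nrow(simp), ], pts[n, ])
    # exhaustive epsilon bound
    expect_lte(max_dev_to_polyline(pts, simp), eps + 1e-12)
  }
})

test_that("dp output size is non-increasing in the tolerance", {
  set.seed(8)
  pts <- cbind(cumsum(rnorm(40)), cumsum(rnorm(40)))
  sizes <- vapply(c(0.1, 0.3, 0.6, 1, 2, 4),
                  function(e) nrow(dp_simplify_open(pts, e)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("dp_simplify_closed recovers square corners and bounds deviation", {
  # square traced with collinear intermediate points
  side <- seq(0, 10, by = 1)
  sq <- rbind(cbind(0, side), cbind(side[-1], 10),
              cbind(10, rev(side)[-1]), cbind(rev(side)[-c(1, 11)], 0))
  cv <- boundary_curve(sq)
  simp <- dp_simplify_closed(cv, 0.4, c(5, 5))
  expect_setequal(paste(simp$points[, 1], simp$points[, 2]),
                  c("0 0", "0 10", "10 10", "10 0"))

  # Hausdorff-style bound on arbitrary closed curves
  set.seed(77)
  for (rep in 1:6) {
    th <- seq(0, 2 * pi, length.out = 120)[-120]
    r <- 8 + 2 * sin(sample(2:6, 1) * th + runif(1, 0, pi))
    pts <- cbind(10 + r * sin(th), 10 + r * cos(th))
    eps <- runif(1, 0.3, 2)
    simp <- dp_simplify_closed(boundary_curve(pts), eps, c(10, 10))
    expect_lte(max_dev_to_polyline(pts, simp$points, closed = TRUE),
               eps + 1e-12)
    # anchors: farthest-from-center vertex must be retained
    far <- pts[which.max(rowSums(sweep(pts, 2, c(10, 10))^2)), ]
    expect_true(any(simp$points[, 1] == far[1] & simp$points[, 2] == far[2]))
  }
})

test_that("closed simplification is stable under cyclic relabeling", {
  th <- seq(0, 2 * pi, length.out = 90)[-90]
  r <- 8 + 2 * sin(3 * th)
  pts <- cbind(10 + r * sin(th), 10 + r * cos(th))
  base <- dp_simplify_closed(boundary_curve(pts), 0.5, c(10, 10))$points
  for (shift in c(10, 41)) {
    rot <- pts[c((shift + 1):nrow(pts), 1:shift), ]
    out <- dp_simplify_closed(boundary_curve(rot), 0.5, c(10, 10))$points
    expect_setequal(paste(out[, 1], out[, 2]), paste(base[, 1], base[, 2]))
  }
})

test_that("tracing plus small-epsilon simplification recovers convex corners", {
  # rasterized axis-aligned rectangle: 4 corners expected (within 2)
  m <- matrix(FALSE, 20, 20); m[5:15, 4:17] <- TRUE
  cv <- trace_boundary(m)
  simp <- dp_simplify_closed(cv, 0.6, roi_centroid(m))
  expect_lte(abs(nrow(simp$points) - 4), 2)
})
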