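test_that("window_hu maps the lung window linearly with clamping", {
  spec <- window_spec(1600, -600)
  # bounds of the window: level -/+ width/2
  expect_equal(window_hu(array(-1400, c(1, 1, 1)), spec)[1], 0)
  expect_equal(window_hu(array(200, c(1, 1, 1)), spec)[1], 255)
  expect_equal(window_hu(array(-2000, c(1, 1, 1)), spec)[1], 0)
  expect_equal(window_hu(array(-600, c(1, 1, 1)), spec)[1], 127.5)
  hu <- array(seq(-2000, 1000, length.out = 60), c(3, 4, 5))
  g <- window_hu(hu, spec)
  expect_identical(dim(g), dim(hu))
  expect_true(all(diff(as.vector(g)) >= 0))  # monotone in HU
  # idempotent: identity window on an already-windowed image
  expect_equal(window_hu(g, window_spec(255, 127.5)), g, tolerance = 1e-12)
  bad <- hu; bad[2, 3, 1] <- NaN
  expect_error(window_hu(bad, spec), "non-finite HU value at voxel \\(1, 2, 0\\)")
})

test_that("binarize thresholds pointwise", {
  z <- matrix(0, 4, 4)
  expect_false(any(binarize(z, 128)))
  expect_true(all(binarize(matrix(255, 4, 4), 128)))
  chk <- matrix(c(0, 255), 4, 4)
  expect_identical(binarize(chk, 128), chk == 255)
})

test_that("extract_rois finds 8-connected components above min_area", {
  m <- matrix(FALSE, 12, 12)
  m[3:7, 3:7] <- TRUE           # 5x5 block
  rois <- extract_rois(m, min_area = 4)
  expect_length(rois, 1L)
  expect_equal(sum(rois[[1]]$pixels), 25)

  m[10, 10] <- TRUE             # isolated speckle below min_area
  expect_length(extract_rois(m, min_area = 4), 1L)

  m2 <- matrix(FALSE, 12, 12)
  m2[2:4, 2:4] <- TRUE
  m2[8:10, 8:10] <- TRUE
  rois2 <- extract_rois(m2, min_area = 4)
  expect_length(rois2, 2L)

  # diagonal contact merges under 8-connectivity, splits under 4
  m3 <- matrix(FALSE, 8, 8)
  m3[2:3, 2:3] <- TRUE
  m3[4:5, 4:5] <- TRUE
  expect_length(extract_rois(m3, min_area = 1), 1L)
  expect_length(extract_rois(m3, min_area = 1, connectivity = 4L), 2L)

  expect_identical(extract_rois(matrix(FALSE, 5, 5)), list())
  # ordering by decreasing area, and area bookkeeping
  m4 <- matrix(FALSE, 20, 20)
  m4[2:4, 2:4] <- TRUE; m4[10:16, 10:16] <- TRUE
  rois4 <- extract_rois(m4, min_area = 1)
  areas <- vapply(rois4, function(r) sum(r$pixels), numeric(1))
  expect_identical(areas, sort(areas, decreasing = TRUE))
  expect_equal(sum(areas), sum(m4))
})

test_that("roi_centroid is the unweighted mean under 0-based pixel centers", {
  m <- matrix(FALSE, 6, 6); m[1:4, 1:4] <- TRUE
  expect_equal(unname(roi_centroid(m)), c(1.5, 1.5))
  m2 <- matrix(FALSE, 10, 10); m2[8, 4] <- TRUE
  expect_equal(unname(roi_centroid(m2)), c(7, 3))
  mL <- matrix(FALSE, 5, 5)
  mL[cbind(c(1, 2, 3, 3), c(1, 1, 1, 2))] <- TRUE  # L-shape at (0,0)..(2,1)
  expect_equal(unname(roi_centroid(mL)), c(1.25, 0.25))
  expect_error(roi_centroid(matrix(FALSE, 3, 3)), "empty")
})

test_that("centroids of centrally-symmetric regions sit at the center", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 15L
    half <- matrix(runif(n * n) < 0.4, n, n)
    sym <- half | half[n:1, n:1]          # point symmetry about the center
    sym[(n + 1) / 2, (n + 1) / 2] <- TRUE
    expect_equal(unname(roi_centroid(sym)), c((n - 1) / 2, (n - 1) / 2))
  }
})

test_that("crop_box is floor-centered with recorded zero padding", {
  vol <- array(seq_len(64^3) %% 251 + 1, c(64, 64, 64))
  box <- crop_box(vol, c(32, 32, 32), 32)
  expect_identical(box$gray, vol[17:48, 17:48, 17:48])
  expect_true(all(box$padding == 0))

  corner <- crop_box(vol, c(0, 0, 0), 32)
  expect_equal(corner$padding[, "low"], c(z = 16L, y = 16L, x = 16L))
  expect_true(all(corner$gray[1:16, , ] == 0))

  # an even-size box centered mid-volume covers the whole volume exactly
  exact <- crop_box(vol[1:32, 1:32, 1:32], c(16, 16, 16), 32)
  expect_identical(exact$gray, vol[1:32, 1:32, 1:32])
  expect_true(all(exact$padding == 0))

  expect_error(crop_box(vol, c(70, 0, 0), 32), "outside the volume")
})

test_that("crop then re-embed restores the overlap region", {
  set.seed(4)
  vol <- array(runif(40^3, 0, 255), c(40, 40, 40))
  for (ctr in list(c(20, 20, 20), c(3, 20, 36))) {
    box <- crop_box(vol, ctr, 16)
    emb <- embed_box(box, dim(vol))
    nz <- emb != 0
    expect_gt(sum(nz), 0)
    expect_equal(emb[nz], vol[nz])
  }
})

test_that("nodule inclusion filters keep 3-30 mm solid grade-!=3 lesions", {
  ann <- data.frame(
    nodule_id = letters[1:6],
    diameter_mm = c(10, 2, 10, 31, 10, 5),
    malignancy = c(3L, 5L, 4L, 4L, 2L, 1L),
    solid = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  out <- filter_nodules(ann)
  expect_identical(out$nodule_id, c("c", "f"))
  expect_identical(out$label, c("malignant", "benign"))
  ann$malignancy[1] <- 6L
  expect_error(filter_nodules(ann), "grade outside 1..5")
})
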