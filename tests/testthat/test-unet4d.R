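test_that("conv2d_ref matches the four-nested-loop evaluation", {
  x1 <- array(1, c(1, 5, 5))
  expect_equal(conv2d_ref(x1, matrix(1, 3, 3), 0, activation = "identity"),
               matrix(9, 3, 3))
  # 1x1 identity kernel reproduces a single-channel input
  set.seed(1)
  xs <- array(rnorm(25), c(1, 5, 5))
  expect_equal(conv2d_ref(xs, matrix(1, 1, 1), 0, activation = "identity"),
               xs[1, , ])
  # random 2-channel input against the direct evaluation
  x <- array(rnorm(2 * 6 * 7), c(2, 6, 7))
  k <- matrix(rnorm(12), 3, 4)
  expect_equal(conv2d_ref(x, k, bias = 0.3, activation = "identity"),
               oracle_conv2d(x, k, bias = 0.3), tolerance = 1e-6)
  # subtracted bias, rectified
  got <- conv2d_ref(x, k, bias = 0.3)
  expect_equal(got, pmax(oracle_conv2d(x, k, 0.3), 0), tolerance = 1e-6)
})

test_that("conv4d_ref matches the six-nested-loop evaluation", {
  # delta kernel passes the valid region through
  set.seed(2)
  x <- array(rnorm(1 * 3 * 4 * 5 * 5), c(1, 3, 4, 5, 5))
  delta <- array(0, c(1, 2, 2, 2, 2)); delta[1, 1, 1, 1, 1] <- 1
  expect_equal(conv4d_ref(x, delta, 0, activation = "identity"),
               x[1, 1:2, 1:3, 1:4, 1:4])
  ones <- array(1, c(1, 2, 2, 2, 2))
  expect_true(all(conv4d_ref(array(1, c(1, 3, 3, 3, 3)), ones, 0,
                             activation = "identity") == 16))
  # random multi-channel tensors, extents <= 4
  for (rep in 1:5) {
    d <- c(sample(1:2, 1), sample(2:4, 4, replace = TRUE))
    kd <- c(d[1], vapply(d[-1], function(e) sample(seq_len(e), 1), numeric(1)))
    x <- array(rnorm(prod(d)), d)
    k <- array(rnorm(prod(kd)), kd)
    expect_equal(conv4d_ref(x, k, bias = 0.7, activation = "identity"),
                 oracle_conv4d(x, k, bias = 0.7), tolerance = 1e-5)
  }
})

test_that("the GEMM fast path agrees with the reference convolution", {
  set.seed(3)
  for (rep in 1:5) {
    d <- c(sample(1:3, 1), sample(2:4, 4, replace = TRUE))
    cout <- sample(1:3, 1)
    kd <- c(d[1], vapply(d[-1], function(e) sample(seq_len(e), 1), numeric(1)))
    x <- array(rnorm(prod(d)), d)
    w <- array(rnorm(cout * prod(kd)), c(cout, kd))
    b <- rnorm(cout)
    fast <- conv4d(x, w, b)
    for (co in seq_len(cout)) {
      ref <- conv4d_ref(x, array(w[co, , , , , ], kd), b[co],
                        activation = "identity")
      expect_equal(array(fast[co, , , , ], dim(ref)), ref, tolerance = 1e-10)
    }
  }
  # the single-precision training path stays close to the double path
  x <- array(rnorm(2 * 2 * 8 * 8 * 8), c(2, 2, 8, 8, 8))
  w <- array(rnorm(3 * 2 * 1 * 27), c(3, 2, 1, 3, 3, 3))
  b <- rnorm(3)
  yd <- conv4d(x, w, b, pad = c(0L, 1L, 1L, 1L))
  yf <- radscan:::cpp_conv4d_forward_train(x, w, b, c(0L, 1L, 1L, 1L), FALSE)$y
  expect_equal(yf, yd, tolerance = 1e-5)
})

test_that("conv4d collapses to the 2D formulation on singleton axes", {
  set.seed(4)
  x2 <- array(rnorm(2 * 6 * 6), c(2, 6, 6))
  k2 <- matrix(rnorm(9), 3, 3)
  x4 <- array(x2, c(2, 1, 1, 6, 6))
  k4 <- array(0, c(2, 1, 1, 3, 3))
  k4[1, 1, 1, , ] <- k2; k4[2, 1, 1, , ] <- k2   # kernel shared over channels
  a <- conv4d_ref(x4, k4, bias = 0.2, activation = "identity", bias_sign = "-")
  b <- conv2d_ref(x2, k2, bias = 0.2, activation = "identity", bias_sign = "-")
  expect_equal(array(a, dim(b)), b, tolerance = 1e-10)
})

test_that("conv4d_ref is linear with identity activation and zero bias", {
  set.seed(5)
  d <- c(2, 3, 3, 4, 4); kd <- c(2, 2, 2, 3, 3)
  x <- array(rnorm(prod(d)), d); y <- array(rnorm(prod(d)), d)
  k <- array(rnorm(prod(kd)), kd)
  f <- function(z) conv4d_ref(z, k, 0, activation = "identity")
  expect_equal(f(2.5 * x - 1.3 * y), 2.5 * f(x) - 1.3 * f(y),
               tolerance = 1e-5)
})

test_that("conv dimension and channel mismatches error", {
  x <- array(1, c(2, 3, 3, 3, 3))
  expect_error(conv4d_ref(x, array(1, c(3, 2, 2, 2, 2))), "channels")
  expect_error(conv4d_ref(x, array(1, c(2, 4, 2, 2, 2))), "exceeds")
  expect_error(conv4d(x, array(1, c(1, 3, 1, 1, 1, 1))), "channels")
})

test_that("assemble_input embeds volume and shape matrix deterministically", {
  box <- gen_nodule_volume(synth_config(box_size = 16L), "benign", 5L)
  sm <- nodule_shape_matrix(box)
  s <- assemble_input(box, sm)
  expect_identical(dim(s$tensor), c(1L, 2L, 16L, 16L, 16L))
  expect_equal(s$tensor[1, 1, , , ], box$gray / 255)
  # plane 2: slice k's series replicated across that slice's rows
  for (k in c(1, 8, 16))
    for (y in c(1, 9))
      expect_equal(s$tensor[1, 2, k, y, ], unclass(sm)[k, ])
  # zero in, zero out
  zbox <- nodule_box(array(0, rep(16, 3)), label = "benign")
  zs <- suppressWarnings(
    assemble_input(zbox, build_shape_matrix(vector("list", 16),
                                            matrix(0, 16, 2),
                                            radial_config(16))))
  expect_true(all(zs$tensor == 0))
  expect_error(assemble_input(box, matrix(0, 8, 8)), "does not match")
})

test_that("build_unet exposes a deterministic parameter count", {
  cfg <- unet_config(depth = 3, base_filters = 8, seed = 1)
  m <- build_unet(cfg, input_dim = c(2, 32, 32, 32))
  # closed-form, layer by layer (kernels 2x3x3x3 first, then 1x3x3x3,
  # head 1x1x1x1): frozen value from the architecture arithmetic
  count_conv <- function(cin, cout, k) cout * cin * k + cout
  expected <- count_conv(1, 8, 54) + count_conv(8, 8, 27) +
    count_conv(8, 16, 27) + count_conv(16, 16, 27) +
    count_conv(16, 32, 27) + count_conv(32, 32, 27) +
    count_conv(32, 64, 27) + count_conv(64, 64, 27) +
    count_conv(96, 32, 27) + count_conv(32, 32, 27) +
    count_conv(48, 16, 27) + count_conv(16, 16, 27) +
    count_conv(24, 8, 27) + count_conv(8, 8, 27) +
    count_conv(8, 2, 1)
  expect_identical(m$n_params, expected)
  expect_identical(m$n_params, 365410)
  expect_error(build_unet(unet_config(depth = 3), input_dim = c(2, 20, 20, 20)),
               "divisible")
})

test_that("zero weights give uniform softmax and seeds give determinism", {
  cfg <- unet_config(depth = 1, base_filters = 1, seed = 2)
  m <- build_unet(cfg, input_dim = c(2, 8, 8, 8))
  m$params <- lapply(m$params, function(w) w * 0)
  s <- list(tensor = array(runif(2 * 512), c(1, 2, 8, 8, 8)),
            label = "benign", is_synthetic = FALSE)
  class(s) <- "tensor4d_sample"
  expect_equal(unname(predict(m, s)[1, ]), c(0.5, 0.5))

  m1 <- build_unet(unet_config(depth = 2, base_filters = 4, seed = 7),
                   input_dim = c(2, 16, 16, 16))
  m2 <- build_unet(unet_config(depth = 2, base_filters = 4, seed = 7),
                   input_dim = c(2, 16, 16, 16))
  expect_identical(m1$params, m2$params)
})

test_that("softmax cross-entropy matches closed forms", {
  expect_equal(softmax_cross_entropy(c(0, 0), 1L), log(2))
  expect_equal(softmax_cross_entropy(c(0, 0), 2L), log(2))
  expect_lt(softmax_cross_entropy(c(10, -10), 1L), 1e-4)
  set.seed(6)
  lg <- matrix(rnorm(20), 10, 2)
  lb <- sample(1:2, 10, replace = TRUE)
  expect_gte(softmax_cross_entropy(lg, lb), 0)
  expect_error(softmax_cross_entropy(c(0, 0), 3L), "labels must lie in")
})

test_that("training is seeded, stable, and can overfit a small set", {
  td <- tiny_dataset()
  smp <- td$samples
  cfg <- unet_config(depth = 2, base_filters = 4, epochs = 20,
                     batch_size = 4, lr = 5e-4, seed = 11)
  m0 <- calibrate_unet(build_unet(cfg, input_dim = c(2, 16, 16, 16)), smp)

  # zero epochs: unchanged parameters, empty history
  m_zero <- train_unet(m0, smp, epochs = 0)
  expect_identical(m_zero$params, m0$params)
  expect_identical(nrow(m_zero$history), 0L)

  expect_error(train_unet(m0, smp[1:8]), "single class")

  m <- train_unet(m0, smp)
  expect_true(all(is.finite(m$history$loss)))
  expect_identical(nrow(m$history), 20L)
  # capacity check: training accuracy reaches 1 on 16 separable samples
  expect_gte(max(m$history$accuracy), 1.0)

  # determinism: an identical run reproduces the history exactly
  m_again <- train_unet(m0, smp)
  expect_identical(m$history, m_again$history)

  # argmax on the training set reproduces the labels after overfitting
  probs <- predict(m, smp)
  labels <- vapply(smp, `[[`, character(1), "label")
  expect_equal(colnames(probs)[apply(probs, 1, which.max)], labels)
  # probabilities are a simplex row-wise
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, length(smp)), tolerance = 1e-6)
  # batch prediction equals per-sample prediction
  expect_equal(probs[3, ], predict(m, smp[[3]])[1, ], tolerance = 1e-6)

  expect_error(predict(m, list(structure(list(
    tensor = array(0, c(1, 2, 8, 8, 8)), label = "benign",
    is_synthetic = FALSE), class = "tensor4d_sample"))), "extents")
})
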