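#' Reference 2D convolution
#'
#' Literal single-kernel 2D valid cross-correlation: the kernel is
#' shared across input channels, channel contributions are summed, the
#' scalar bias is subtracted (the historical sign for this formulation;
#' switch with `bias_sign`) and the activation applied:
#' `y[k,l] = phi( sum_c sum_ij w[i,j] x[c, k+i, l+j] - b )`.
#'
#' @param input numeric `(C, H, W)` array or `(H, W)` matrix.
#' @param kernel numeric `(Kh, Kw)` matrix.
#' @param bias scalar.
#' @param activation `"relu"` (default) or `"identity"`.
#' @param bias_sign `"-"` (default) or `"+"`.
#' @return `(H - Kh + 1) x (W - Kw + 1)` feature map.
#' @export
conv2d_ref <- function(input, kernel, bias = 0,
                       activation = c("relu", "identity"),
                       bias_sign = c("-", "+")) {
  activation <- match.arg(activation)
  bias_sign <- match.arg(bias_sign)
  if (length(dim(input)) == 2L) input <- array(input, c(1L, dim(input)))
  if (length(dim(input)) != 3L) stopf("input must be (C, H, W)")
  d <- dim(input); kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh > d[2L] || kw > d[3L]) stopf("kernel exceeds input extent")
  ho <- d[2L] - kh + 1L; wo <- d[3L] - kw + 1L
  y <- matrix(0, ho, wo)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    slab <- input[, i:(i + ho - 1L), j:(j + wo - 1L), drop = FALSE]
    y <- y + kernel[i, j] * colSums(slab)  # sum over channels
  }
  y <- y + if (bias_sign == "-") -bias else bias
  if (activation == "relu") y[y < 0] <- 0
  y
}

#' Reference generalized 4D convolution
#'
#' Valid cross-correlation over the four axes (R, D, H, W) of a
#' multi-channel rank-5 input, with channel contributions summed into a
#' single output map, additive bias (the sign is switchable) and
#' activation. This is the slow, transparent reference; the network's
#' training path uses a GEMM formulation checked against it.
#'
#' @param input numeric `(C, R, D, H, W)` array.
#' @param kernel numeric `(C, Kr, Kd, Kh, Kw)` array.
#' @param bias scalar.
#' @param activation `"relu"` (default) or `"identity"`.
#' @param bias_sign `"+"` (default) or `"-"`.
#' @return `(R-Kr+1, D-Kd+1, H-Kh+1, W-Kw+1)` feature map.
#' @export
conv4d_ref <- function(input, kernel, bias = 0,
                       activation = c("relu", "identity"),
                       bias_sign = c("+", "-")) {
  activation <- match.arg(activation)
  bias_sign <- match.arg(bias_sign)
  d <- dim(input); kd <- dim(kernel)
  if (length(d) != 5L || length(kd) != 5L) stopf("input/kernel must be rank 5")
  if (d[1L] != kd[1L])
    stopf("input has %d channels but kernel expects %d", d[1L], kd[1L])
  if (any(kd[-1L] > d[-1L])) stopf("kernel exceeds input extent")
  od <- d[-1L] - kd[-1L] + 1L
  y <- array(0, od)
  for (r in seq_len(kd[2L])) for (dd in seq_len(kd[3L]))
    for (i in seq_len(kd[4L])) for (j in seq_len(kd[5L])) {
      slab <- input[, r:(r + od[1L] - 1L), dd:(dd + od[2L] - 1L),
                    i:(i + od[3L] - 1L), j:(j + od[4L] - 1L), drop = FALSE]
      wv <- kernel[, r, dd, i, j]
      y <- y + array(colSums(slab * wv), od)
    }
  y <- y + if (bias_sign == "-") -bias else bias
  if (activation == "relu") y[y < 0] <- 0
  y
}

#' Fast multi-filter 4D convolution (GEMM path)
#'
#' The layer operation used inside the network: a bank of `C_out`
#' generalized 4D kernels applied with optional zero padding, one bias
#' per filter. Equivalent, filter by filter, to [conv4d_ref()].
#'
#' @param input numeric `(C_in, R, D, H, W)` array.
#' @param weights numeric `(C_out, C_in, Kr, Kd, Kh, Kw)` array.
#' @param bias numeric length `C_out`.
#' @param pad integer length 4, zero padding per axis (both sides).
#' @param activation `"relu"`, `"identity"`.
#' @param bias_sign `"+"` or `"-"`.
#' @return `(C_out, Ro, Do, Ho, Wo)` array.
#' @export
conv4d <- function(input, weights, bias = NULL, pad = c(0L, 0L, 0L, 0L),
                   activation = c("identity", "relu"),
                   bias_sign = c("+", "-")) {
  activation <- match.arg(activation)
  bias_sign <- match.arg(bias_sign)
  if (length(dim(input)) != 5L) stopf("input must be rank 5 (C, R, D, H, W)")
  if (length(dim(weights)) != 6L) stopf("weights must be rank 6")
  if (is.null(bias)) bias <- numeric(dim(weights)[1L])
  y <- cpp_conv4d_forward(input, weights, bias, as.integer(pad),
                          if (bias_sign == "+") 1 else -1)
  if (activation == "relu") y[y < 0] <- 0
  y
}

#' Assemble the joint 4D classification tensor
#'
#' Fuses a nodule box with its shape matrix into one rank-5 sample: a
#' single input channel whose fourth axis has extent 2, plane 1 holding
#' the grayscale volume rescaled to `[0, 1]` and plane 2 the shape
#' matrix broadcast along the in-plane row axis (slice k's radial series
#' is replicated across the rows of slice k). The embedding is
#' deterministic and plane 1 recovers the volume exactly.
#'
#' @param box a [nodule_box()] (`Z = Y = X` cube).
#' @param shape a [build_shape_matrix()] result with `Z` rows and `X`
#'   columns, values in `[0, 1]`.
#' @return an object of class `tensor4d_sample`: fields `tensor`
#'   (`1 x 2 x Z x Y x X`), `label`, `is_synthetic`.
#' @export
assemble_input <- function(box, shape) {
  g <- box$gray
  d <- dim(g)
  shape <- unclass(shape)
  if (nrow(shape) != d[1L] || ncol(shape) != d[3L])
    stopf("shape matrix %dx%d does not match box %s",
          nrow(shape), ncol(shape), paste(d, collapse = "x"))
  if (min(shape) < 0 || max(shape) > 1)
    stopf("shape matrix must be normalized to [0, 1]")
  tensor <- array(0, c(1L, 2L, d))
  tensor[1L, 1L, , , ] <- g / 255
  tensor[1L, 2L, , , ] <- aperm(array(shape, c(d[1L], d[3L], d[2L])),
                                c(1L, 3L, 2L))
  structure(list(tensor = tensor, label = box$label, is_synthetic = FALSE),
            class = "tensor4d_sample")
}

#' U-Net hyper-parameters
#'
#' @param depth number of encoder levels (each halves the three spatial
#'   axes); the ablation grid of interest is depth 3 or 4.
#' @param base_filters filters at the first level, doubling per level
#'   (grid: 4 or 8).
#' @param n_classes number of output classes C (>= 2).
#' @param lr Adam learning rate. The default is deliberately small:
#'   with a global-average head and balanced classes, aggressive rates
#'   drive small networks into the uniform-prediction saddle (loss
#'   pinned at `ln 2`) and leave them there.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization and shuffling.
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(depth = 3L, base_filters = 8L, n_classes = 2L,
                        lr = 5e-4, epochs = 30L, batch_size = 4L,
                        seed = 0L) {
  if (depth < 1L) stopf("depth must be >= 1")
  if (base_filters < 1L) stopf("base_filters must be >= 1")
  if (n_classes < 2L) stopf("n_classes must be >= 2")
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 n_classes = as.integer(n_classes),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "unet_config")
}

# ordered conv-layer descriptors for the architecture; the first conv
# spans the full extent of the plane axis (valid, collapsing it), all
# later kernels are 1 there; spatial kernels are 3 with same-padding
unet_layers <- function(cfg, input_dim) {
  r_in <- input_dim[1L]
  f <- function(l) cfg$base_filters * 2L^(l - 1L)
  layers <- list()
  add <- function(id, cin, cout, kernel, pad, act = "relu") {
    layers[[id]] <<- list(id = id, cin = cin, cout = cout,
                          kernel = kernel, pad = pad, act = act)
  }
  cin <- 1L
  for (l in seq_len(cfg$depth)) {
    kr <- if (l == 1L) r_in else 1L
    add(paste0("enc", l, "a"), cin, f(l), c(kr, 3L, 3L, 3L), c(0L, 1L, 1L, 1L))
    add(paste0("enc", l, "b"), f(l), f(l), c(1L, 3L, 3L, 3L), c(0L, 1L, 1L, 1L))
    cin <- f(l)
  }
  fb <- cfg$base_filters * 2L^cfg$depth
  add("bota", cin, fb, c(1L, 3L, 3L, 3L), c(0L, 1L, 1L, 1L))
  add("botb", fb, fb, c(1L, 3L, 3L, 3L), c(0L, 1L, 1L, 1L))
  up <- fb
  for (l in rev(seq_len(cfg$depth))) {
    add(paste0("dec", l, "a"), up + f(l), f(l), c(1L, 3L, 3L, 3L), c(0L, 1L, 1L, 1L))
    add(paste0("dec", l, "b"), f(l), f(l), c(1L, 3L, 3L, 3L), c(0L, 1L, 1L, 1L))
    up <- f(l)
  }
  add("head", cfg$base_filters, cfg$n_classes, c(1L, 1L, 1L, 1L),
      c(0L, 0L, 0L, 0L), act = "identity")
  layers
}

#' Build a 4D U-Net classifier
#'
#' Encoder of `depth` levels (two generalized 4D convolutions then 2x
#' max-pooling of the three spatial axes per level, filters doubling
#' from `base_filters`), a two-convolution bottleneck, a matching
#' decoder with nearest-neighbor upsampling and skip concatenation, and
#' a 1-extent convolution head whose output is globally averaged into C
#' logits followed by softmax. The extent-2 plane axis is fused by the
#' first convolution and never pooled. Initialization is He-style and
#' fully determined by `cfg$seed`.
#'
#' @param cfg a [unet_config()].
#' @param input_dim integer `(R, D, H, W)` extents of one sample's
#'   single-channel tensor (default `c(2, 32, 32, 32)`); the spatial
#'   extents must be divisible by `2^depth`.
#' @return an object of class `radscan_unet` with elements `cfg`,
#'   `input_dim`, `params` and `n_params`.
#' @export
build_unet <- function(cfg = unet_config(), input_dim = c(2L, 32L, 32L, 32L)) {
  input_dim <- as.integer(input_dim)
  div <- 2L^cfg$depth
  if (any(input_dim[2:4] %% div != 0L) || any(input_dim[2:4] %/% div < 1L))
    stopf("spatial extents (%s) must be divisible by 2^depth = %d",
          paste(input_dim[2:4], collapse = ", "), div)
  layers <- unet_layers(cfg, input_dim)
  params <- list()
  with_local_seed(cfg$seed, {
    for (ly in layers) {
      fan_in <- ly$cin * prod(ly$kernel)
      params[[paste0(ly$id, "_w")]] <-
        array(rnorm(ly$cout * fan_in, sd = sqrt(2 / fan_in)),
              c(ly$cout, ly$cin, ly$kernel))
      params[[paste0(ly$id, "_b")]] <- numeric(ly$cout)
    }
  })
  n_params <- sum(vapply(params, length, numeric(1L)))
  structure(list(cfg = cfg, input_dim = input_dim, layers = layers,
                 params = params, n_params = n_params, opt = NULL,
                 classes = c("benign", "malignant")),
            class = "radscan_unet")
}

#' @export
print.radscan_unet <- function(x, ...) {
  cat(sprintf("<radscan_unet> depth %d, base %d filters, %s input, %d parameters\n",
              x$cfg$depth, x$cfg$base_filters,
              paste(x$input_dim, collapse = "x"), x$n_params))
  invisible(x)
}

#' Data-dependent initialization of a U-Net
#'
#' Standardizes the network layer by layer on a handful of calibration
#' samples: each convolution's weights and bias are rescaled so that
#' every channel's pre-activation has approximately zero mean and unit
#' variance over the calibration batch. The correction is folded into
#' the parameters as constants, so unlike per-sample normalization it
#' preserves the inter-sample amplitude contrasts the classifier feeds
#' on, while keeping the deep stack well-conditioned from the first
#' update. Deterministic given the model and the samples.
#'
#' @param model a [build_unet()] model (untrained).
#' @param samples list of `tensor4d_sample` objects (typically the
#'   training set).
#' @param n_calibration how many samples to use (default 8).
#' @return the model with calibrated parameters.
#' @export
calibrate_unet <- function(model, samples, n_calibration = 8L) {
  xs <- lapply(head(samples, n_calibration), `[[`, "tensor")
  p <- model$params
  conv_cal <- function(hs, id) {
    ly <- model$layers[[id]]
    w <- p[[paste0(id, "_w")]]; b <- p[[paste0(id, "_b")]]
    ys <- lapply(hs, function(h) cpp_conv4d_forward(h, w, b, ly$pad, 1))
    C <- dim(ys[[1L]])[1L]
    all <- do.call(cbind, lapply(ys, function(y) matrix(y, C)))
    mu <- rowMeans(all)
    sdv <- sqrt(pmax(rowMeans(all^2) - mu^2, 1e-8))
    p[[paste0(id, "_w")]] <<- w / sdv          # recycles over filters
    p[[paste0(id, "_b")]] <<- (b - mu) / sdv
    lapply(ys, function(y) {
      d <- dim(y)
      z <- array((matrix(y, C) - mu) / sdv, d)
      if (ly$act == "relu") z[z < 0] <- 0
      z
    })
  }
  hs <- xs
  skips <- list()
  for (l in seq_len(model$cfg$depth)) {
    hs <- conv_cal(hs, paste0("enc", l, "a"))
    hs <- conv_cal(hs, paste0("enc", l, "b"))
    skips[[l]] <- hs
    hs <- lapply(hs, function(h) cpp_maxpool3_forward(h)$y)
  }
  hs <- conv_cal(hs, "bota")
  hs <- conv_cal(hs, "botb")
  for (l in rev(seq_len(model$cfg$depth))) {
    hs <- lapply(hs, upsample3)
    hs <- Map(concat_channels, hs, skips[[l]])
    hs <- conv_cal(hs, paste0("dec", l, "a"))
    hs <- conv_cal(hs, paste0("dec", l, "b"))
  }
  conv_cal(hs, "head")
  model$params <- p
  model$calibrated <- TRUE
  model
}

upsample3 <- function(x) {
  d <- dim(x)
  x[, , rep(seq_len(d[3L]), each = 2L), rep(seq_len(d[4L]), each = 2L),
    rep(seq_len(d[5L]), each = 2L), drop = FALSE]
}

upsample3_backward <- function(gy) {
  d <- dim(gy)
  i3 <- seq(1L, d[3L], 2L); i4 <- seq(1L, d[4L], 2L); i5 <- seq(1L, d[5L], 2L)
  gx <- gy[, , i3, i4, i5, drop = FALSE] * 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1)
    gx <- gx + gy[, , i3 + a, i4 + b, i5 + cc, drop = FALSE]
  gx
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L] + db[1L], da[-1L]))
  out[seq_len(da[1L]), , , , ] <- a
  out[da[1L] + seq_len(db[1L]), , , , ] <- b
  out
}

# forward pass; cache everything needed for backprop when training
unet_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  cache <- list(kptr = list(), xdim = list(), pre = list(), pool = list(),
                skip_dim = list())
  conv_step <- function(h, id) {
    ly <- model$layers[[id]]
    res <- cpp_conv4d_forward_train(h, p[[paste0(id, "_w")]],
                                    p[[paste0(id, "_b")]], ly$pad, keep_cache)
    z <- res$y
    if (keep_cache) {
      cache$kptr[[id]] <<- res$k
      cache$xdim[[id]] <<- dim(h)
    }
    if (ly$act == "relu") {
      if (keep_cache) cache$pre[[id]] <<- z
      z[z < 0] <- 0
    }
    z
  }
  h <- x
  skips <- list()
  for (l in seq_len(model$cfg$depth)) {
    h <- conv_step(h, paste0("enc", l, "a"))
    h <- conv_step(h, paste0("enc", l, "b"))
    skips[[l]] <- h
    pl <- cpp_maxpool3_forward(h)
    if (keep_cache) cache$pool[[l]] <- list(idx = pl$idx, xdim = dim(h))
    h <- pl$y
  }
  h <- conv_step(h, "bota")
  h <- conv_step(h, "botb")
  for (l in rev(seq_len(model$cfg$depth))) {
    h <- upsample3(h)
    if (keep_cache) cache$skip_dim[[l]] <- dim(h)[1L]
    h <- concat_channels(h, skips[[l]])
    h <- conv_step(h, paste0("dec", l, "a"))
    h <- conv_step(h, paste0("dec", l, "b"))
  }
  h <- conv_step(h, "head")
  logits <- apply(h, 1L, mean)
  list(logits = logits, feat_dim = dim(h), cache = if (keep_cache) cache)
}

# gradient of all parameters for one sample given dLoss/dlogits
unet_backward <- function(model, fwd, dlogits) {
  p <- model$params
  cache <- fwd$cache
  grads <- list()
  conv_back <- function(g, id) {
    ly <- model$layers[[id]]
    if (ly$act == "relu") g <- g * (cache$pre[[id]] > 0)
    bk <- cpp_conv4d_backward_train(cache$kptr[[id]], p[[paste0(id, "_w")]],
                                    g, ly$pad, cache$xdim[[id]],
                                    id != "enc1a")
    grads[[paste0(id, "_w")]] <<- bk$gw
    grads[[paste0(id, "_b")]] <<- bk$gb
    bk$gx
  }
  fd <- fwd$feat_dim
  npos <- prod(fd[-1L])
  g <- array(rep(dlogits / npos, npos), fd)
  g <- conv_back(g, "head")
  # decoder blocks in reverse forward order: dec1 ran last
  g_skip <- vector("list", model$cfg$depth)
  for (l in seq_len(model$cfg$depth)) {
    g <- conv_back(g, paste0("dec", l, "b"))
    g <- conv_back(g, paste0("dec", l, "a"))
    nup <- cache$skip_dim[[l]]
    g_skip[[l]] <- g[nup + seq_len(dim(g)[1L] - nup), , , , , drop = FALSE]
    g <- upsample3_backward(g[seq_len(nup), , , , , drop = FALSE])
  }
  g <- conv_back(g, "botb")
  g <- conv_back(g, "bota")
  for (l in rev(seq_len(model$cfg$depth))) {
    g <- cpp_maxpool3_backward(g, cache$pool[[l]]$idx, cache$pool[[l]]$xdim)
    g <- g + g_skip[[l]]
    g <- conv_back(g, paste0("enc", l, "b"))
    g <- conv_back(g, paste0("enc", l, "a"))
  }
  grads
}

#' Softmax cross-entropy loss
#'
#' `-log softmax(logits)[label]`, averaged over the batch; the loss the
#' network trains with, turning C logits into class probabilities.
#'
#' @param logits numeric length-C vector or `n x C` matrix.
#' @param labels integer class indices in `1..C` (or a factor).
#' @return scalar mean loss.
#' @export
softmax_cross_entropy <- function(logits, labels) {
  if (is.null(dim(logits))) logits <- matrix(logits, 1L)
  labels <- as.integer(labels)
  C <- ncol(logits)
  if (any(labels < 1L | labels > C))
    stopf("labels must lie in 1..%d", C)
  z <- logits - apply(logits, 1L, max)
  lse <- log(rowSums(exp(z)))
  mean(lse - z[cbind(seq_along(labels), labels)])
}

softmax <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

sample_label_index <- function(model, s) {
  i <- match(s$label, model$classes)
  if (is.na(i)) stopf("unknown label '%s'", s$label)
  i
}

#' Train a 4D U-Net
#'
#' Minibatch Adam on the softmax cross-entropy, fully determined by the
#' model's seed: shuffling, initialization and updates are reproducible.
#' With `epochs = 0` the model is returned unchanged with an empty
#' history.
#'
#' @param model a [build_unet()] model.
#' @param samples list of [assemble_input()] samples; both classes must
#'   be present.
#' @param epochs,batch_size,lr overrides of the model's configured
#'   values.
#' @return the model with updated parameters and a `history` data frame
#'   (`epoch`, `loss`, `accuracy`).
#' @export
train_unet <- function(model, samples, epochs = NULL, batch_size = NULL,
                       lr = NULL) {
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- lr %||% cfg$lr
  n <- length(samples)
  if (n < 2L) stopf("need at least 2 samples")
  y <- vapply(samples, function(s) sample_label_index(model, s), integer(1L))
  if (length(unique(y)) < 2L)
    stopf("training set contains a single class")
  model$history <- data.frame(epoch = integer(), loss = numeric(),
                              accuracy = numeric())
  if (epochs == 0L) return(model)
  if (is.null(model$opt))
    model$opt <- list(m = lapply(model$params, function(w) w * 0),
                      v = lapply(model$params, function(w) w * 0), t = 0L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  with_local_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L
      for (b0 in seq(1L, n, by = batch_size)) {
        idx <- perm[b0:min(b0 + batch_size - 1L, n)]
        grads <- NULL
        for (i in idx) {
          fwd <- unet_forward(model, samples[[i]]$tensor, keep_cache = TRUE)
          pr <- softmax(fwd$logits)
          ep_loss <- ep_loss - log(max(pr[y[i]], 1e-300))
          if (which.max(pr) == y[i]) ep_correct <- ep_correct + 1L
          dl <- pr
          dl[y[i]] <- dl[y[i]] - 1
          g <- unet_backward(model, fwd, dl)
          grads <- if (is.null(grads)) g else
            Map(`+`, grads, g)
        }
        grads <- lapply(grads, function(g) g / length(idx))
        model$opt$t <- model$opt$t + 1L
        t <- model$opt$t
        for (nm in names(model$params)) {
          model$opt$m[[nm]] <- b1 * model$opt$m[[nm]] + (1 - b1) * grads[[nm]]
          model$opt$v[[nm]] <- b2 * model$opt$v[[nm]] + (1 - b2) * grads[[nm]]^2
          mhat <- model$opt$m[[nm]] / (1 - b1^t)
          vhat <- model$opt$v[[nm]] / (1 - b2^t)
          model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      model$history <- rbind(model$history,
                             data.frame(epoch = ep, loss = ep_loss / n,
                                        accuracy = ep_correct / n))
      if (!all(is.finite(model$history$loss)))
        stopf("training diverged (non-finite loss) at epoch %d", ep)
    }
  })
  model
}

#' Class probabilities for nodule samples
#'
#' @param object a [build_unet()] model (trained or not).
#' @param samples list of [assemble_input()] samples or a single sample.
#' @param ... unused.
#' @return `n x C` matrix of probabilities (rows sum to 1), columns
#'   named by class.
#' @export
predict.radscan_unet <- function(object, samples, ...) {
  if (inherits(samples, "tensor4d_sample")) samples <- list(samples)
  out <- t(vapply(samples, function(s) {
    if (!identical(dim(s$tensor)[-1L], as.integer(object$input_dim)))
      stopf("sample extents (%s) do not match the model input (%s)",
            paste(dim(s$tensor)[-1L], collapse = "x"),
            paste(object$input_dim, collapse = "x"))
    softmax(unet_forward(object, s$tensor)$logits)
  }, numeric(object$cfg$n_classes)))
  colnames(out) <- if (object$cfg$n_classes == 2L) object$classes else
    paste0("class", seq_len(object$cfg$n_classes))
  out
}
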