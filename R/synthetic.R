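#' Synthetic nodule generator settings
#'
#' Phantom nodules are star-shaped solids: each slice's boundary radius
#' is `r(theta, z) = R(z) * (1 + a * g(theta))`, where `R(z)` follows an
#' ellipsoidal profile along the slice axis and `g` is a unit-bounded
#' sum of random-phase angular harmonics. The class amplitude `a`
#' controls spiculation: smooth boundaries for benign-like nodules,
#' spiky ones for malignant-like, which is the morphological cue
#' radiologists use and the signal the radial scan encodes. Interior
#' voxels are bright soft-tissue gray, exterior voxels dark parenchyma,
#' both with additive noise, mimicking the contrast after lung
#' windowing.
#'
#' @param n_per_class samples per class for [gen_dataset()].
#' @param box_size cube edge in voxels (default 32).
#' @param base_radius_range equatorial radius range in voxels; default
#'   26-32% of the box edge, so the nodule fills the box the way a
#'   cropped nodule fills its fixed-size box and individual lobes span
#'   several pixels.
#' @param amplitude_benign,amplitude_malignant spiculation amplitude as
#'   a fraction of the radius (defaults 0.05 and 0.35).
#' @param spiculation_lobes number of angular harmonics (orders
#'   `3 .. lobes + 2`). The default keeps lobe wavelengths above the
#'   pixel pitch at desk-scale box sizes; boundary detail narrower than
#'   a pixel cannot survive binarization and tracing.
#' @param texture_noise_sd additive gray-level noise SD (0-255 scale).
#' @param seed integer master seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 50L, box_size = 32L,
                         base_radius_range = NULL,
                         amplitude_benign = 0.05,
                         amplitude_malignant = 0.35,
                         spiculation_lobes = 3L,
                         texture_noise_sd = 15,
                         seed = 0L) {
  if (is.null(base_radius_range))
    base_radius_range <- c(0.26, 0.32) * box_size
  if (amplitude_benign < 0 || amplitude_benign >= 1 ||
      amplitude_malignant < 0 || amplitude_malignant >= 1)
    stopf("spiculation amplitudes must lie in [0, 1)")
  structure(list(n_per_class = as.integer(n_per_class),
                 box_size = as.integer(box_size),
                 base_radius_range = base_radius_range,
                 amplitude_benign = amplitude_benign,
                 amplitude_malignant = amplitude_malignant,
                 spiculation_lobes = as.integer(spiculation_lobes),
                 texture_noise_sd = texture_noise_sd,
                 seed = as.integer(seed)), class = "synth_config")
}

#' Generate one synthetic nodule box
#'
#' Fully deterministic given `(cfg, label, seed)`: the same call always
#' returns a bit-identical box.
#'
#' @param cfg a [synth_config()].
#' @param label `"benign"` or `"malignant"` (selects the spiculation
#'   amplitude).
#' @param seed integer seed for this nodule.
#' @return a [nodule_box()].
#' @export
gen_nodule_volume <- function(cfg, label = c("benign", "malignant"),
                              seed = 0L) {
  label <- match.arg(label)
  a <- if (label == "benign") cfg$amplitude_benign else cfg$amplitude_malignant
  n <- cfg$box_size
  ctr <- (n - 1) / 2  # 0-based center of the box
  with_local_seed(seed, {
    r0 <- runif(1L, cfg$base_radius_range[1L], cfg$base_radius_range[2L])
    if (r0 * (1 + a) > n / 2 - 1)
      stopf("radius %.1f with amplitude %.2f exceeds the box", r0, a)
    zsemi <- runif(1L, 0.65, 0.9) * (n / 2 - 1)
    orders <- 3L:(cfg$spiculation_lobes + 2L)
    w <- runif(length(orders))
    w <- w / sum(w)           # |g(theta)| <= 1
    phase <- runif(length(orders), 0, 2 * pi)
    gray <- array(0, rep(n, 3L))
    yx <- expand.grid(row = 0:(n - 1L), col = 0:(n - 1L))
    dr <- yx$row - ctr; dc <- yx$col - ctr
    rho <- sqrt(dr^2 + dc^2)
    theta <- atan2(dr, dc)
    gmod <- rep(0, length(theta))
    for (h in seq_along(orders))
      gmod <- gmod + w[h] * cos(orders[h] * theta + phase[h])
    for (z in 0:(n - 1L)) {
      dz <- (z - ctr) / zsemi
      if (abs(dz) >= 1) { inside <- rep(FALSE, nrow(yx)) } else {
        rz <- r0 * sqrt(1 - dz^2)
        inside <- rho <= rz * (1 + a * gmod)
      }
      vals <- ifelse(inside, 200, 40) + rnorm(nrow(yx), sd = cfg$texture_noise_sd)
      gray[z + 1L, , ] <- matrix(pmin(255, pmax(0, vals)), n, n)
    }
    box <- nodule_box(gray, spacing = c(1, 1, 1), label = label,
                      center_voxel = rep(n %/% 2L, 3L))
    # analytic boundary model, for provenance and model-level checks:
    # r(theta, z) = R(z) * (1 + a * sum_h w_h cos(orders_h theta + phase_h))
    attr(box, "morphology") <- list(r0 = r0, zsemi = zsemi,
                                    amplitude = a, orders = orders,
                                    weights = w, phases = phase)
    box
  })
}

#' Analytic boundary radii of a synthetic nodule
#'
#' Evaluates the generator's continuous boundary model
#' `r(theta, z) = R(z) (1 + a g(theta))` for a box produced by
#' [gen_nodule_volume()], before any rasterization.
#'
#' @param box a synthetic [nodule_box()].
#' @param theta angles in radians.
#' @param z 0-based slice index (default: the equatorial slice).
#' @return radii in voxels (0 where the slice is outside the nodule).
#' @export
synthetic_boundary_radius <- function(box, theta, z = NULL) {
  m <- attr(box, "morphology")
  if (is.null(m)) stopf("box carries no synthetic morphology model")
  n <- dim(box$gray)[1L]
  ctr <- (n - 1) / 2
  if (is.null(z)) z <- ctr
  dz <- (z - ctr) / m$zsemi
  if (abs(dz) >= 1) return(rep(0, length(theta)))
  g <- rep(0, length(theta))
  for (h in seq_along(m$orders))
    g <- g + m$weights[h] * cos(m$orders[h] * theta + m$phases[h])
  m$r0 * sqrt(1 - dz^2) * (1 + m$amplitude * g)
}

#' Generate a labelled synthetic dataset
#'
#' @param cfg a [synth_config()].
#' @param n_benign,n_malignant class counts; default `n_per_class` each.
#'   Unequal counts (e.g. the 616:281 archive imbalance, scaled down)
#'   exercise the SMOTE stage.
#' @return list with `boxes` (list of [nodule_box()]) and `manifest`
#'   (data frame `id`, `label`, `seed`); regenerating from the manifest
#'   with [gen_from_manifest()] reproduces the dataset exactly.
#' @export
gen_dataset <- function(cfg, n_benign = cfg$n_per_class,
                        n_malignant = cfg$n_per_class) {
  if (n_benign < 1L || n_malignant < 1L) stopf("need at least 1 per class")
  n <- n_benign + n_malignant
  manifest <- data.frame(
    id = sprintf("synth%04d", seq_len(n)),
    label = rep(c("benign", "malignant"), c(n_benign, n_malignant)),
    seed = cfg$seed * 100000L + seq_len(n))
  list(boxes = gen_from_manifest(manifest, cfg), manifest = manifest)
}

#' @rdname gen_dataset
#' @param manifest a manifest data frame written by [gen_dataset()].
#' @export
gen_from_manifest <- function(manifest, cfg) {
  lapply(seq_len(nrow(manifest)), function(i)
    gen_nodule_volume(cfg, manifest$label[i], manifest$seed[i]))
}

#' Turn nodule boxes into classifier-ready samples
#'
#' Runs binarization, boundary tracing, simplification and radial
#' scanning on every box ([nodule_shape_matrix()]) and fuses each with
#' its gray volume ([assemble_input()]).
#'
#' @param boxes list of [nodule_box()].
#' @param radial_cfg a [radial_config()]; `n_angles` must equal the box
#'   edge so the shape matrix stacks square.
#' @param ... passed to [nodule_shape_matrix()].
#' @return list of `tensor4d_sample` objects.
#' @export
prepare_samples <- function(boxes, radial_cfg = NULL, ...) {
  if (is.null(radial_cfg))
    radial_cfg <- radial_config(n_angles = dim(boxes[[1L]]$gray)[1L])
  lapply(boxes, function(b)
    assemble_input(b, nodule_shape_matrix(b, radial_cfg, ...)))
}
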