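# Independent oracles and geometry builders used across the suite.

# literal six-nested-loop valid cross-correlation over (c, r, d, i, j)
# for a rank-5 input and a single rank-5 kernel
oracle_conv4d <- function(x, k, bias = 0) {
  d <- dim(x); kd <- dim(k)
  od <- d[-1L] - kd[-1L] + 1L
  y <- array(0, od)
  for (r in 1:od[1]) for (dd in 1:od[2]) for (i in 1:od[3]) for (j in 1:od[4]) {
    s <- 0
    for (cc in 1:d[1])
      for (kr in 1:kd[2]) for (kq in 1:kd[3])
        for (ki in 1:kd[4]) for (kj in 1:kd[5])
          s <- s + k[cc, kr, kq, ki, kj] *
            x[cc, r + kr - 1, dd + kq - 1, i + ki - 1, j + kj - 1]
    y[r, dd, i, j] <- s + bias
  }
  y
}

# four-nested-loop evaluation of the shared-kernel 2D formulation,
# bias subtracted
oracle_conv2d <- function(x, k, bias = 0) {
  d <- dim(x); kh <- nrow(k); kw <- ncol(k)
  ho <- d[2] - kh + 1L; wo <- d[3] - kw + 1L
  y <- matrix(0, ho, wo)
  for (kk in 1:ho) for (l in 1:wo) {
    s <- 0
    for (cc in 1:d[1]) for (i in 1:kh) for (j in 1:kw)
      s <- s + k[i, j] * x[cc, kk + i - 1, l + j - 1]
    y[kk, l] <- s - bias
  }
  y
}

# exhaustive max distance from every original vertex to the simplified
# polyline (open) or polygon (closed)
max_dev_to_polyline <- function(orig, simp, closed = FALSE) {
  segs <- if (closed) rbind(simp, simp[1, ]) else simp
  worst <- 0
  for (i in seq_len(nrow(orig))) {
    best <- Inf
    for (s in seq_len(nrow(segs) - 1L)) {
      a <- segs[s, ]; b <- segs[s + 1L, ]
      ab <- b - a; len2 <- sum(ab^2)
      t <- if (len2 == 0) 0 else
        min(1, max(0, sum((orig[i, ] - a) * ab) / len2))
      best <- min(best, sqrt(sum((orig[i, ] - a - t * ab)^2)))
    }
    worst <- max(worst, best)
  }
  worst
}

# dense polygonal approximations of standard shapes, (row, col) vertices
polygon_circle <- function(center = c(0, 0), radius = 1, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * sin(th), center[2] + radius * cos(th))
}

polygon_ellipse <- function(center = c(0, 0), a = 4, b = 2, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + b * sin(th), center[2] + a * cos(th))
}

raster_disk <- function(size, center, radius) {
  m <- matrix(FALSE, size, size)
  for (i in seq_len(size)) for (j in seq_len(size))
    if ((i - 1 - center[1])^2 + (j - 1 - center[2])^2 <= radius^2)
      m[i, j] <- TRUE
  m
}

# small prepared dataset shared by the slower tests (built once per run)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- gen_dataset(synth_config(box_size = 16L, n_per_class = 8L, seed = 42L))
      cache <<- list(ds = ds, samples = prepare_samples(ds$boxes))
    }
    cache
  }
})
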