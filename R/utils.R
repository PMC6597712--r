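# internal helpers shared across modules

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Pixel-integrated symmetric 2-D Gaussian punctum. `mass` is the total
# integrated intensity; the rendered matrix sums to `mass` up to the tails
# falling outside the image. Coordinates are 0-based pixel centers.
render_punctum <- function(nrow, ncol, row0, col0, sigma, mass = 1) {
  # pixel i (0-based) spans [i - 0.5, i + 0.5] around its center
  r <- stats::pnorm(seq_len(nrow) - 1 + 0.5, row0, sigma) -
       stats::pnorm(seq_len(nrow) - 1 - 0.5, row0, sigma)
  c <- stats::pnorm(seq_len(ncol) - 1 + 0.5, col0, sigma) -
       stats::pnorm(seq_len(ncol) - 1 - 0.5, col0, sigma)
  mass * outer(r, c)
}

# Fraction of a unit-mass punctum landing in its center pixel; used to
# convert a peak-height amplitude into an integrated mass.
punctum_peak_fraction <- function(sigma) {
  (stats::pnorm(0.5, 0, sigma) - stats::pnorm(-0.5, 0, sigma))^2
}

# Gaussian smoothing of a matrix via EBImage::filter2 with a brush sized to
# fit the image (EBImage::gblur fails when the kernel exceeds the image).
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  size <- 2L * ceiling(2.5 * sigma) + 1L
  size <- min(size, 2L * floor((min(dim(m)) - 1L) / 2L) + 1L)
  if (size < 3L) return(m)
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(m, k, boundary = "replicate"))
}

# Strict 3-D local maxima of an array (frame, row, col) over the full
# 26-neighborhood. Returns a logical array.
local_maxima_3d <- function(a) {
  d <- dim(a)
  res <- array(TRUE, d)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  for (dt in -1:1) for (dr in -1:1) for (dc in -1:1) {
    if (dt == 0 && dr == 0 && dc == 0) next
    nb <- pad[(2:(d[1] + 1)) + dt, (2:(d[2] + 1)) + dr,
              (2:(d[3] + 1)) + dc, drop = FALSE]
    res <- res & (a > nb)
  }
  res
}

# Strict 2-D local maxima over the 8-neighborhood.
local_maxima_2d <- function(m) {
  d <- dim(m)
  res <- matrix(TRUE, d[1], d[2])
  pad <- matrix(-Inf, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (m > pad[(2:(d[1] + 1)) + dr, (2:(d[2] + 1)) + dc])
  }
  res
}

# Mean of trace values with times inside [window[1], window[2]] (closed on
# the left, open on the right so adjacent windows do not share samples).
window_mean <- function(trace, window, min_samples = 3L, what = "window") {
  sel <- times(trace) >= window[1] & times(trace) < window[2]
  if (sum(sel) < min_samples)
    stop(sprintf("%s [%g, %g) contains %d samples (need >= %d)",
                 what, window[1], window[2], sum(sel), min_samples))
  mean(values(trace)[sel])
}

# Euclidean distance (px) of each mask pixel to the nearest background
# pixel, treating everything beyond the image border as background.
mask_distance <- function(mask) {
  pad <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
  d <- as.matrix(EBImage::distmap(pad, metric = "euclidean"))
  d[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
}

# Bilinear interpolation of matrix m at continuous 0-based (row, col).
bilinear <- function(m, row, col) {
  r0 <- pmin(pmax(floor(row), 0), nrow(m) - 1)
  c0 <- pmin(pmax(floor(col), 0), ncol(m) - 1)
  r1 <- pmin(r0 + 1, nrow(m) - 1)
  c1 <- pmin(c0 + 1, ncol(m) - 1)
  fr <- pmin(pmax(row - r0, 0), 1)
  fc <- pmin(pmax(col - c0, 0), 1)
  v00 <- m[cbind(r0 + 1, c0 + 1)]
  v01 <- m[cbind(r0 + 1, c1 + 1)]
  v10 <- m[cbind(r1 + 1, c0 + 1)]
  v11 <- m[cbind(r1 + 1, c1 + 1)]
  v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
}
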