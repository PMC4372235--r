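# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, min = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L)
    stopf("'%s' must be a single numeric value", name)
  if (finite && !is.finite(x))
    stopf("'%s' must be finite (got %s)", name, format(x))
  if (strict && x <= min)
    stopf("'%s' must be > %g (got %g)", name, min, x)
  if (!strict && x < min)
    stopf("'%s' must be >= %g (got %g)", name, min, x)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_scalar(x, name, min = min)
  if (x != round(x)) stopf("'%s' must be an integer count", name)
  as.integer(x)
}

# Wrap angles to [0, 2*pi).
wrap_angle <- function(theta) theta %% (2 * pi)

# Reflect coordinates into [0, hi] (fold across both boundaries, any
# number of crossings).
reflect_into <- function(x, hi) {
  p <- 2 * hi
  x <- x %% p
  ifelse(x > hi, p - x, x)
}

# Lower-median convention: for even n return the smaller of the two
# central order statistics.
lower_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) stopf("lower_median of empty vector")
  x[[(n + 1L) %/% 2L]]
}

# Bilinear interpolation of image values at fractional (row, col)
# positions (1-based pixel-center coordinates). Points outside the image
# are clamped to the border.
bilinear <- function(image, row, col) {
  H <- nrow(image); W <- ncol(image)
  row <- pmin(pmax(row, 1), H)
  col <- pmin(pmax(col, 1), W)
  r0 <- pmin(floor(row), H - 1L); c0 <- pmin(floor(col), W - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- image[cbind(r0, c0)]
  i10 <- image[cbind(r0 + 1, c0)]
  i01 <- image[cbind(r0, c0 + 1)]
  i11 <- image[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}

# Centroid and principal axes of a labelled region, from the second
# moments of its pixel coordinates. Returns centroid (row, col), unit
# long/short axis vectors and the half-extents of the pixel cloud
# projected on each axis.
mask_axes <- function(mask, cell_id) {
  idx <- which(mask == cell_id, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("cell %s not present in mask", cell_id)
  ctr <- colMeans(idx)
  xy <- sweep(idx, 2, ctr)
  cv <- crossprod(xy) / nrow(xy)
  eg <- eigen(cv, symmetric = TRUE)
  long <- eg$vectors[, 1L]
  short <- eg$vectors[, 2L]
  # orient axes deterministically
  if (long[which.max(abs(long))] < 0) long <- -long
  if (short[which.max(abs(short))] < 0) short <- -short
  u <- xy %*% long
  v <- xy %*% short
  list(centroid = ctr, long = long, short = short,
       half_long = max(abs(u)), half_short = max(abs(v)),
       n_pixels = nrow(idx))
}

# Binary dilation of a logical matrix by `iter` applications of a 3x3
# structuring element (used to define background regions).
dilate3 <- function(m, iter = 1L) {
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(iter)) {
    out <- m
    out[-1, ] <- out[-1, ] | m[-H, ]
    out[-H, ] <- out[-H, ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -W]
    out[, -W] <- out[, -W] | m[, -1]
    # diagonals
    out[-1, -1] <- out[-1, -1] | m[-H, -W]
    out[-H, -W] <- out[-H, -W] | m[-1, -1]
    out[-1, -W] <- out[-1, -W] | m[-H, -1]
    out[-H, -1] <- out[-H, -1] | m[-1, -W]
    m <- out
  }
  m
}

# Derive a child seed from a master seed and an index, staying within
# 32-bit signed integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}
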