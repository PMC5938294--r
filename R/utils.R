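# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# logit and inverse logit on probabilities strictly inside (0, 1)
logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# half-up rounding to integer (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# rotation matrix from intrinsic z-y-x Euler angles (radians)
euler_rotation <- function(angles) {
  a <- angles[1]; b <- angles[2]; c <- angles[3]
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  rz %*% ry %*% rx
}

# separable Gaussian blur of a 3D array; sigma in voxels per axis,
# zero-padded boundaries (fields of interest vanish near the edges)
gaussian_blur3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    arr <- apply_conv_axis(arr, k, axis)
  }
  arr
}

# trilinear interpolation of a 3D array at fractional (1-based) indices;
# points outside the grid get `outside`
trilinear_sample <- function(arr, idx, outside = 0) {
  d <- dim(arr)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(outside, nrow(idx))
  if (!any(ok)) return(out)
  p <- idx[ok, , drop = FALSE]
  lo <- pmin(floor(p), matrix(rep(d - 1L, each = nrow(p)), nrow(p)))
  fr <- p - lo
  acc <- numeric(nrow(p))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx == 1) fr[, 1] else 1 - fr[, 1]) *
         (if (dy == 1) fr[, 2] else 1 - fr[, 2]) *
         (if (dz == 1) fr[, 3] else 1 - fr[, 3])
    lin <- (lo[, 3] + dz - 1) * d[1] * d[2] + (lo[, 2] + dy - 1) * d[1] +
      (lo[, 1] + dx)
    acc <- acc + w * arr[lin]
  }
  out[ok] <- acc
  out
}

# separable 2D Gaussian smoothing of a matrix, zero padding, sigma in pixels
gauss_smooth2 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(mm) {
    n <- nrow(mm)
    out <- matrix(0, n, ncol(mm))
    for (off in -r:r) {
      src <- (1:n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[off + r + 1L] * mm[src[ok], ]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

# convolve along one axis with kernel k (odd length), zero padding
apply_conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (off in -r:r) {
    w <- k[off + r + 1L]
    src <- (1:n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + w * m[src[ok], ]
  }
  inv <- order(perm)
  aperm(array(out, da), inv)
}
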