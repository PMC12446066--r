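# Internal separable filtering and grid interpolation used across modules.
# Convention everywhere: arrays are indexed (z, y, x); voxel centers sit at
# integer coordinates 0, 1, ..., n-1 along each axis.

gauss_kernel1d <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# index reflection for 'reflect' boundary handling (d c b a | a b c d)
reflect_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  p <- 2L * n
  j <- ((j - 1L) %% p + p) %% p  # 0-based mod 2n
  ifelse(j < n, j + 1L, p - j)
}

# dense matrix applying a 1D convolution with reflect boundaries along an axis
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in -r:r) {
    j <- reflect_index(i + o, n)
    idx <- cbind(i, j)
    K[idx] <- K[idx] + kernel[o + r + 1L]
  }
  K
}

apply_axis_matrix <- function(arr, K, axis) {
  d <- dim(arr)
  if (axis == 1L) {
    array(K %*% matrix(arr, d[1], d[2] * d[3]), c(nrow(K), d[2], d[3]))
  } else if (axis == 2L) {
    a <- aperm(arr, c(2, 1, 3))
    a <- array(K %*% matrix(a, d[2], d[1] * d[3]), c(nrow(K), d[1], d[3]))
    aperm(a, c(2, 1, 3))
  } else {
    array(matrix(arr, d[1] * d[2], d[3]) %*% t(K), c(d[1], d[2], nrow(K)))
  }
}

conv_axis <- function(arr, kernel, axis) {
  apply_axis_matrix(arr, conv_matrix(dim(arr)[axis], kernel), axis)
}

# separable Gaussian blur of a 3D array, sigma in voxels per axis (z,y,x)
gaussian_blur3 <- function(arr, sigma, truncate = 4) {
  for (ax in 1:3) {
    if (sigma[ax] > 0) arr <- conv_axis(arr, gauss_kernel1d(sigma[ax], truncate), ax)
  }
  arr
}

# 2D variants for per-slice filtering (matrix indexed (y, x))
conv_mat2 <- function(m, kernel, axis) {
  K <- conv_matrix(dim(m)[axis], kernel)
  if (axis == 1L) K %*% m else m %*% t(K)
}

gaussian_blur2 <- function(m, sigma, truncate = 4) {
  k <- gauss_kernel1d(sigma, truncate)
  conv_mat2(conv_mat2(m, k, 1L), k, 2L)
}

# Catmull-Rom cubic convolution weights for fractional offset t in [0,1);
# columns correspond to sample offsets -1, 0, 1, 2.
cubic_weights <- function(t) {
  cbind(0.5 * (-t + 2 * t^2 - t^3),
        0.5 * (2 - 5 * t^2 + 3 * t^3),
        0.5 * (t + 4 * t^2 - 3 * t^3),
        0.5 * (-t^2 + t^3))
}

# Sample a 3D array at arbitrary (z,y,x) coordinates (0-based voxel centers).
# order 0 = nearest, 1 = trilinear, 3 = cubic (Catmull-Rom). Samples that fall
# outside the grid contribute 0 (zero fill).
interp_volume <- function(data, coords, order = 1) {
  stopifnot(order %in% c(0, 1, 3))
  d <- dim(data)
  n <- nrow(coords)
  if (n == 0L) return(numeric(0))
  if (order == 0) {
    idx <- floor(coords + 0.5)
    ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
          idx[, 2] >= 0 & idx[, 2] < d[2] &
          idx[, 3] >= 0 & idx[, 3] < d[3]
    out <- numeric(n)
    out[ok] <- data[idx[ok, , drop = FALSE] + 1]
    return(out)
  }
  lo <- floor(coords)
  f <- coords - lo
  if (order == 1) {
    offs <- 0:1
    W <- lapply(1:3, function(ax) cbind(1 - f[, ax], f[, ax]))
  } else {
    offs <- -1:2
    W <- lapply(1:3, function(ax) cubic_weights(f[, ax]))
  }
  out <- numeric(n)
  for (a in seq_along(offs)) {
    iz <- lo[, 1] + offs[a]
    wz <- W[[1]][, a]
    okz <- iz >= 0 & iz < d[1]
    for (b in seq_along(offs)) {
      iy <- lo[, 2] + offs[b]
      wzy <- wz * W[[2]][, b]
      okzy <- okz & iy >= 0 & iy < d[2]
      for (cc in seq_along(offs)) {
        ix <- lo[, 3] + offs[cc]
        ok <- okzy & ix >= 0 & ix < d[3]
        if (!any(ok)) next
        w <- wzy[ok] * W[[3]][ok, cc]
        out[ok] <- out[ok] + w * data[cbind(iz[ok], iy[ok], ix[ok]) + 1]
      }
    }
  }
  out
}

# full coordinate grid (0-based) for a block of output voxels; rows ordered
# z-fastest (R array order) so results can be assigned directly
grid_coords <- function(zs, ys, xs) {
  cbind(rep(zs, times = length(ys) * length(xs)),
        rep(rep(ys, each = length(zs)), times = length(xs)),
        rep(xs, each = length(zs) * length(ys)))
}
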