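# Conversion of segmentation masks into reduced 3D point clouds.

# shift a matrix by (dy, dx), zero-filling vacated entries
shift_mat <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0, ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# 2D Canny edge detector on a (y, x) matrix: Gaussian smoothing, Sobel
# gradients, non-maximum suppression along the quantized gradient direction,
# and hysteresis linking (thresholds as fractions of the peak magnitude).
canny2d <- function(img, sigma = 1.0, low_frac = 0.1, high_frac = 0.2) {
  g <- gaussian_blur2(img, sigma)
  smooth3 <- c(1, 2, 1) / 4
  diff3 <- c(1, 0, -1) / 2           # derivative along increasing index
  gy <- conv_mat2(conv_mat2(g, diff3, 1L), smooth3, 2L)
  gx <- conv_mat2(conv_mat2(g, smooth3, 1L), diff3, 2L)
  mag <- sqrt(gx^2 + gy^2)
  peak <- max(mag)
  if (peak <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  ang <- atan2(gy, gx)               # gradient direction
  sector <- (round(ang / (pi / 4)) %% 4)  # 0: +-x, 1: diag(+,+), 2: +-y, 3: diag(+,-)
  n1 <- matrix(0, nrow(img), ncol(img)); n2 <- n1
  for (s in 0:3) {
    d <- switch(as.character(s),
                "0" = c(0L, 1L), "1" = c(1L, 1L), "2" = c(1L, 0L), "3" = c(1L, -1L))
    sel <- sector == s
    n1[sel] <- shift_mat(mag, d[1], d[2])[sel]
    n2[sel] <- shift_mat(mag, -d[1], -d[2])[sel]
  }
  keep <- mag >= n1 & mag >= n2 & mag > 0
  weak <- keep & (mag >= low_frac * peak)
  strong <- keep & (mag >= high_frac * peak)
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  # hysteresis: 8-connected weak components that touch a strong pixel
  lab <- label_components(array(weak, c(dim(img), 1L)), 26L)[, , 1]
  good <- unique(lab[strong])
  good <- good[good > 0L]
  weak & (lab %in% good)
}

#' Sample surface points from a segmentation mask
#'
#' Binarizes the mask and applies a 2D Canny edge filter to every z-slice;
#' each edge pixel becomes one `(z, y, x)` point. The mask should be on an
#' isotropic grid (resample label volumes with [resample_isotropic()] first).
#' Point order is deterministic: z ascending, then row-major (y, then x)
#' within each slice.
#'
#' @param mask a `clem_labels` (any positive label is foreground).
#' @param canny_sigma Gaussian scale of the Canny filter in pixels.
#' @return A [point_cloud()] in pixel space (`step_nm` = grid step).
#' @export
surface_points <- function(mask, canny_sigma = 1.0) {
  stopifnot(is_labels(mask))
  vs <- mask$voxel_size
  step <- if (max(vs) - min(vs) < 1e-6 * max(vs)) vs[1] else {
    warning("surface_points expects an isotropic grid; using the z step")
    vs[1]
  }
  d <- dim(mask$labels)
  pts <- vector("list", d[1])
  for (z in seq_len(d[1])) {
    edges <- canny2d((mask$labels[z, , ] > 0L) * 1.0, sigma = canny_sigma)
    if (!any(edges)) next
    idx <- which(edges, arr.ind = TRUE)             # (y, x), 1-based
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    pts[[z]] <- cbind(z - 1, idx[, 1] - 1, idx[, 2] - 1)
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts)) pts <- matrix(numeric(0), 0L, 3L)
  point_cloud(pts, space = "pixel", step_nm = step)
}

#' Uniform point-cloud downsampling
#'
#' Keeps every k-th point starting with the 0th, so the output has
#' `ceiling(N / k)` points at input indices `0, k, 2k, ...`.
#'
#' @param pc a [point_cloud()].
#' @param k sampling period (integer >= 1); the sampling frequency is `1/k`.
#' @return Downsampled `clem_points`.
#' @export
uniform_downsample <- function(pc, k) {
  stopifnot(inherits(pc, "clem_points"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1")
  n <- nrow(pc$points)
  if (n == 0L) return(pc)
  point_cloud(pc$points[seq(1L, n, by = k), , drop = FALSE],
              space = pc$space, step_nm = pc$step_nm, source = pc$source)
}

#' Voxel-grid binning of a point cloud
#'
#' Partitions space into an `s`-sized grid anchored at the coordinate origin
#' (so clouds from different modalities share commensurate grids); every
#' occupied cell yields exactly one point, the mean of the points it
#' encloses. Output order is deterministic (cells sorted by z, y, x).
#'
#' @param pc a [point_cloud()].
#' @param s integer `(z, y, x)` cell size in grid units (default 15^3).
#' @return Binned `clem_points`.
#' @export
voxel_bin <- function(pc, s = c(15, 15, 15)) {
  stopifnot(inherits(pc, "clem_points"))
  s <- as.numeric(s)
  if (length(s) == 1L) s <- rep(s, 3L)
  if (any(s < 1)) stop("bin sizes must be >= 1")
  p <- pc$points
  if (nrow(p) == 0L) return(pc)
  cell <- cbind(floor(p[, 1] / s[1]), floor(p[, 2] / s[2]), floor(p[, 3] / s[3]))
  ord <- order(cell[, 1], cell[, 2], cell[, 3])
  cell <- cell[ord, , drop = FALSE]
  p <- p[ord, , drop = FALSE]
  key <- cumsum(c(TRUE, rowSums(abs(diff(cell))) > 0))
  out <- rowsum(p, key, reorder = FALSE) / tabulate(key)
  point_cloud(out, space = pc$space, step_nm = pc$step_nm, source = pc$source)
}

#' Statistical outlier removal
#'
#' Computes every point's mean distance to its `n_neighbors` nearest
#' neighbors and removes points whose statistic exceeds
#' `mean + std_ratio * sd` over the cloud.
#'
#' @param pc a [point_cloud()].
#' @param n_neighbors neighborhood size (default 20).
#' @param std_ratio standard-deviation multiplier (default 2.0).
#' @return Filtered `clem_points`; if the cloud has `<= n_neighbors` points
#'   it is returned unchanged with a warning.
#' @export
remove_statistical_outliers <- function(pc, n_neighbors = 20L, std_ratio = 2.0) {
  stopifnot(inherits(pc, "clem_points"))
  p <- pc$points
  n <- nrow(p)
  k <- as.integer(n_neighbors)
  if (n <= k) {
    warning("point cloud has <= n_neighbors points; returning unchanged")
    return(pc)
  }
  sq <- rowSums(p^2)
  stat <- numeric(n)
  chunk <- max(1L, as.integer(2e7 / n))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * p[rows, , drop = FALSE] %*% t(p)
    d2[d2 < 0] <- 0
    stat[rows] <- apply(d2, 1L, function(x)
      mean(sqrt(sort(x, partial = seq_len(k + 1L))[2:(k + 1L)])))
  }
  keep <- stat <= mean(stat) + std_ratio * sd(stat)
  point_cloud(p[keep, , drop = FALSE], space = pc$space,
              step_nm = pc$step_nm, source = pc$source)
}
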