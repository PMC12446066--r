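# Registration-quality metrics and robustness protocols: intersected
# volumes, mesh centroids, characteristic lengths, landmark errors, the
# landmark-noise significance experiment, instance ablation, and the
# proximity-accuracy correlation.

#' Intersected volume of two masks
#'
#' Counts voxels that are foreground in both masks and converts to
#' cubic micrometres via the (common) voxel volume.
#'
#' @param fm_mask,em_mask `clem_labels` on the same grid with the same voxel
#'   size; any positive label is foreground.
#' @return Overlap volume in um^3.
#' @export
overlap_volume <- function(fm_mask, em_mask) {
  stopifnot(is_labels(fm_mask), is_labels(em_mask))
  if (!identical(dim(fm_mask$labels), dim(em_mask$labels)) ||
      any(abs(fm_mask$voxel_size - em_mask$voxel_size) > 1e-9))
    stop("masks must share grid and voxel size")
  n <- sum(fm_mask$labels > 0L & em_mask$labels > 0L)
  n * prod(fm_mask$voxel_size) * 1e-9
}

#' Total foreground volume of a mask in um^3
#'
#' @param mask a `clem_labels`.
#' @return Volume in um^3.
#' @export
mask_volume_um3 <- function(mask) {
  stopifnot(is_labels(mask))
  sum(mask$labels > 0L) * prod(mask$voxel_size) * 1e-9
}

# Vertices of the level-`level` isosurface of a 3D scalar/binary array:
# for every grid edge whose endpoint values straddle the level, the linearly
# interpolated crossing point (the unique marching-cubes vertex set). The
# array is zero-padded so surfaces close at the volume border. Coordinates
# are 0-based voxel units (z, y, x).
isosurface_vertices <- function(arr, level = 0.5) {
  d <- dim(arr)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  verts <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dim(pad)[ax]
    idx_a <- lapply(dim(pad), seq_len); idx_a[[ax]] <- 1:(n - 1)
    idx_b <- lapply(dim(pad), seq_len); idx_b[[ax]] <- 2:n
    a <- do.call(`[`, c(list(pad), idx_a, list(drop = FALSE)))
    b <- do.call(`[`, c(list(pad), idx_b, list(drop = FALSE)))
    cross <- (a < level & b >= level) | (a >= level & b < level)
    if (!any(cross)) next
    w <- which(cross, arr.ind = TRUE)
    t_frac <- (level - a[cross]) / (b[cross] - a[cross])
    coord <- w - 2  # 0-based original coords of the edge start
    coord[, ax] <- coord[, ax] + t_frac
    verts[[ax]] <- coord
  }
  out <- do.call(rbind, verts)
  if (is.null(out)) matrix(numeric(0), 0L, 3L) else out
}

#' Mesh centroid of a segmentation mask
#'
#' Extracts the level-0.5 isosurface vertices of the binarized mask (the
#' marching-cubes vertex set: one linearly interpolated point per grid edge
#' crossing the level) and returns the unweighted mean vertex position,
#' scaled to nm.
#'
#' @param mask non-empty `clem_labels`.
#' @return Length-3 numeric `(z, y, x)` centroid in nm.
#' @export
mesh_centroid <- function(mask) {
  stopifnot(is_labels(mask))
  if (!any(mask$labels > 0L)) stop("mask is empty")
  v <- isosurface_vertices((mask$labels > 0L) * 1.0, 0.5)
  unname(colMeans(v) * mask$voxel_size)
}

#' Euclidean distance between mesh centroids
#'
#' @param a,b non-empty `clem_labels`.
#' @return Distance in nm (symmetric in its arguments).
#' @export
centroid_distance <- function(a, b) {
  sqrt(sum((mesh_centroid(a) - mesh_centroid(b))^2))
}

#' Characteristic length of a segmented structure
#'
#' `L = V^(1/3)`: the edge length of the cube with the structure's volume,
#' used to compare centroid errors to structure size.
#'
#' @param V volume in um^3 (>= 0); vectorized.
#' @return Characteristic length in um.
#' @export
characteristic_length <- function(V) {
  if (any(V < 0)) stop("volume must be non-negative")
  V^(1 / 3)
}

#' Per-pair landmark registration errors
#'
#' Applies a fitted transform to the moving landmarks and returns the
#' Euclidean distance to each paired fixed landmark. Distances are reported
#' in nm when the clouds are in nm, or in pixel units scaled by `step_nm`
#' when available.
#'
#' @param lm_moving,lm_fixed paired [point_cloud()]s (equal counts).
#' @param tr the transform to evaluate (same units as the clouds).
#' @return Numeric vector of per-pair distances.
#' @export
landmark_errors <- function(lm_moving, lm_fixed, tr) {
  Pm <- as_points_matrix(lm_moving)
  Pf <- as_points_matrix(lm_fixed)
  if (nrow(Pm) != nrow(Pf)) stop("landmark sets must be paired (equal counts)")
  d <- sqrt(rowSums((transform_points_matrix(tr, Pm) - Pf)^2))
  if (inherits(lm_moving, "clem_points") && lm_moving$space == "pixel" &&
      !is.na(lm_moving$step_nm)) d <- d * lm_moving$step_nm
  d
}

#' Landmark placement-noise significance experiment
#'
#' For each noise level `n`, both landmark sets are perturbed with seeded
#' isotropic Gaussian offsets (mean 0, sd `n` pixels per axis), the error
#' distributions of an automated and a manual transform are computed, and a
#' two-sided two-sample Student's t-test (pooled variance) compares them.
#' Placement noise at which the two methods become statistically
#' indistinguishable bounds the practical accuracy of manual annotation.
#'
#' @param lm_moving,lm_fixed paired [point_cloud()]s in pixel units.
#' @param tr_auto,tr_manual the two transforms to compare.
#' @param n_pixels vector of noise standard deviations in pixels (>= 0).
#' @param seeds RNG seeds; each (n, seed) cell is perturbed independently.
#' @return Data frame with columns `n_pixels`, `seed`, `p_value`,
#'   `mean_auto`, `mean_manual`.
#' @export
landmark_noise_experiment <- function(lm_moving, lm_fixed, tr_auto, tr_manual,
                                      n_pixels = 0:10, seeds = 1:5) {
  if (any(n_pixels < 0)) stop("noise levels must be >= 0")
  Pm <- as_points_matrix(lm_moving)
  Pf <- as_points_matrix(lm_fixed)
  if (nrow(Pm) != nrow(Pf)) stop("landmark sets must be paired (equal counts)")
  rows <- list()
  for (n in n_pixels) for (s in seeds) {
    offs <- with_seed(s * 1000L + as.integer(round(n)), {
      list(m = matrix(rnorm(length(Pm), 0, n), ncol = 3),
           f = matrix(rnorm(length(Pf), 0, n), ncol = 3))
    })
    m2 <- Pm + offs$m
    f2 <- Pf + offs$f
    e_auto <- sqrt(rowSums((transform_points_matrix(tr_auto, m2) - f2)^2))
    e_man <- sqrt(rowSums((transform_points_matrix(tr_manual, m2) - f2)^2))
    p <- tryCatch(t.test(e_auto, e_man, var.equal = TRUE)$p.value,
                  error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      n_pixels = n, seed = s, p_value = p,
      mean_auto = mean(e_auto), mean_manual = mean(e_man))
  }
  do.call(rbind, rows)
}

# per-instance centroids (0-based voxel coords) of a label volume
instance_centroids <- function(labels) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  w <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  cents <- t(vapply(ids, function(i)
    colMeans(w[lab == i, , drop = FALSE]) - 1, numeric(3)))
  rownames(cents) <- ids
  cents
}

#' Remove a fraction of instances from a label volume
#'
#' `mode = "random"` removes `round(fraction * n)` instances uniformly at
#' random (seeded); `"peripheral"` / `"central"` rank instances by the
#' distance of their centroid from the overall foreground centroid and
#' remove the farthest / nearest first.
#'
#' @param labels instance `clem_labels`.
#' @param fraction fraction to remove, in `[0, 1)`.
#' @param mode `"random"`, `"peripheral"` or `"central"`.
#' @param seed RNG seed (used by `"random"` only).
#' @return `clem_labels` with the selected instances zeroed.
#' @export
ablate_instances <- function(labels, fraction, mode = c("random", "peripheral", "central"),
                             seed = 1L) {
  stopifnot(is_labels(labels))
  mode <- match.arg(mode)
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  ids <- sort(setdiff(unique(as.vector(labels$labels)), 0L))
  k <- round(fraction * length(ids))
  if (k == 0L) return(labels)
  drop_ids <- if (mode == "random") {
    with_seed(seed, sample(ids, k))
  } else {
    cents <- instance_centroids(labels$labels)
    fg <- colMeans(which(labels$labels > 0L, arr.ind = TRUE) - 1)
    d <- sqrt(rowSums(sweep(cents, 2L, fg)^2))
    ord <- order(d, decreasing = (mode == "peripheral"))
    ids[ord[seq_len(k)]]
  }
  out <- labels$labels
  out[out %in% drop_ids] <- 0L
  label_volume(out, labels$voxel_size)
}

#' Correlation of target-to-landmark proximity with registration accuracy
#'
#' For each target mask, computes the distance from its mesh centroid to the
#' nearest landmark-mask voxel and rank-correlates (Spearman) these
#' proximities with the supplied per-target centroid distances. A strong
#' positive correlation would indicate that accuracy degrades away from the
#' landmark organelles.
#'
#' @param targets list of >= 3 non-empty `clem_labels`, one per target.
#' @param landmark_mask `clem_labels` of the landmark organelles (same
#'   physical space as the targets).
#' @param centroid_distances numeric vector of per-target registration
#'   errors (nm), same length as `targets`.
#' @return Spearman's rho.
#' @export
proximity_correlation <- function(targets, landmark_mask, centroid_distances) {
  if (length(targets) < 3L) stop("need at least 3 targets")
  if (length(centroid_distances) != length(targets))
    stop("one centroid distance per target required")
  lm_nm <- sweep(which(landmark_mask$labels > 0L, arr.ind = TRUE) - 1, 2L,
                 landmark_mask$voxel_size, "*")
  prox <- vapply(targets, function(tg) {
    cen <- mesh_centroid(tg)
    sqrt(min(rowSums(sweep(lm_nm, 2L, cen)^2)))
  }, numeric(1))
  cor(prox, centroid_distances, method = "spearman")
}
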