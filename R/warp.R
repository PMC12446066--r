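# Application of fitted transforms to intensity volumes: inverse-mapping
# affine warps, 3D thin-plate-spline warps (chunked), and resampling onto
# the EM grid.

new_tps_transform <- function(control, affine, translation, weights) {
  control <- matrix(as.numeric(as.matrix(control)), ncol = 3)
  affine <- matrix(as.numeric(as.matrix(affine)), 3, 3)
  weights <- matrix(as.numeric(as.matrix(weights)), ncol = 3)
  structure(list(control = control, affine = affine,
                 translation = as.numeric(translation), weights = weights,
                 units = "pixel", step_nm = NA_real_),
            class = "tps_transform")
}

# evaluate a TPS map at Q (N x 3): f(q) = t + q A + sum_j |q - c_j| w_j
tps_eval <- function(tr, Q) {
  U <- sqrt(dist2_matrix(Q, tr$control))
  sweep(Q %*% tr$affine + U %*% tr$weights, 2L, tr$translation, "+")
}

#' Fit a 3D thin-plate spline from control-point pairs
#'
#' Solves the TPS interpolation system with the 3D biharmonic kernel
#' `phi(r) = r` and zero regularization, so the fitted map reproduces every
#' control pair exactly. The solution decomposes into an affine part and
#' kernel weights `W` obeying the side conditions `sum(W) = 0` and
#' `t(W) %*% control = 0`; when the pairs follow an affine map the kernel
#' weights vanish.
#'
#' @param source_ctrl,target_ctrl paired `M x 3` point sets (or
#'   [point_cloud()]s), `M >= 4`, not coplanar.
#' @return Object of class `tps_transform` mapping source to target.
#' @export
tps_fit <- function(source_ctrl, target_ctrl) {
  C <- as_points_matrix(source_ctrl)
  Yt <- as_points_matrix(target_ctrl)
  M <- nrow(C)
  if (nrow(Yt) != M) stop("control point sets must be paired (equal counts)")
  if (M < 4L) stop("need at least 4 control pairs")
  P <- cbind(1, C)
  if (qr(P)$rank < 4L)
    stop("control points are coplanar; the TPS system is singular")
  K <- sqrt(dist2_matrix(C, C))
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(Yt, matrix(0, 4, 3))
  sol <- tryCatch(solve(L, rhs),
                  error = function(e) stop("TPS system is singular: ", conditionMessage(e)))
  new_tps_transform(control = C, affine = sol[(M + 2):(M + 4), , drop = FALSE],
                    translation = sol[M + 1, ], weights = sol[seq_len(M), , drop = FALSE])
}

# resolve output geometry: list(shape, voxel_size); default = input geometry
out_geometry <- function(v, out_shape, out_voxel) {
  if (is.null(out_shape)) out_shape <- dim(vol_data(v))
  if (is.null(out_voxel)) out_voxel <- v$voxel_size
  list(shape = as.integer(out_shape), voxel = as.numeric(out_voxel))
}

# generic inverse-mapping warp: `inv_map` takes output-voxel coords (0-based)
# and returns input-grid coords; executed over z-slabs to bound memory
warp_by_inverse_map <- function(v, inv_map, out_shape, order, slab = 16L) {
  arr <- vol_data(v) * 1.0
  out <- array(0, out_shape)
  ys <- seq_len(out_shape[2]) - 1
  xs <- seq_len(out_shape[3]) - 1
  for (z0 in seq(0L, out_shape[1] - 1L, by = slab)) {
    zs <- z0:min(z0 + slab - 1L, out_shape[1] - 1L)
    p <- grid_coords(zs, ys, xs)
    vals <- interp_volume(arr, inv_map(p), order = order)
    out[zs + 1L, , ] <- array(vals, c(length(zs), out_shape[2], out_shape[3]))
  }
  out
}

#' Warp a volume through a rigid or affine transform
#'
#' Inverse-projection warping: every output voxel `p` samples the input
#' volume at `T^-1(p)` by spline interpolation of the requested order
#' (0 nearest, 1 trilinear, 3 cubic); samples outside the input grid are 0.
#' Transform and grids are in the same isotropic pixel space.
#'
#' @param v input `clem_volume`.
#' @param tr invertible `rigid_transform` or `affine_transform` (pixel units)
#'   mapping input to output coordinates.
#' @param out_shape output `(z, y, x)` shape; default = input shape.
#' @param out_voxel output voxel size; default = input voxel size.
#' @param order interpolation order, one of 0, 1, 3 (default 3).
#' @return Warped `clem_volume` on the output grid.
#' @export
affine_warp_volume <- function(v, tr, out_shape = NULL, out_voxel = NULL,
                               order = 3) {
  stopifnot(inherits(v, "clem_volume") || is_labels(v))
  if (!order %in% c(0, 1, 3)) stop("order must be 0, 1 or 3")
  inv <- invert_transform(tr)
  geo <- out_geometry(v, out_shape, out_voxel)
  out <- warp_by_inverse_map(v, function(p) transform_points_matrix(inv, p),
                             geo$shape, order)
  volume(out, geo$voxel, channel = if (is_labels(v)) "" else v$channel)
}

#' Warp a volume through a thin-plate-spline field
#'
#' The field must be fitted in the *output* space, mapping output-grid
#' coordinates back to input-grid coordinates (inverse mapping): fit it with
#' [tps_fit()] from registered control points in the output space to their
#' original input-space positions. The output grid is split into
#' `chunks` (default 2 x 2 x 2 = 8) sub-blocks processed sequentially to
#' bound memory; because evaluation is pointwise, the chunked result is
#' bit-identical to the monolithic one.
#'
#' @param v input `clem_volume`.
#' @param field a `tps_transform` (output coords -> input coords).
#' @param out_shape,out_voxel output geometry; default = input geometry.
#' @param chunks integer `(z, y, x)` chunk counts.
#' @param order interpolation order, one of 0, 1, 3 (default 1).
#' @param grid_step approximate-grid accelerator: when `> 1`, the TPS map is
#'   evaluated on a coarse grid with this voxel step and linearly
#'   interpolated to all voxels before sampling; `0` (default) evaluates the
#'   spline exactly at every voxel.
#' @return Warped `clem_volume`.
#' @export
tps_warp_volume <- function(v, field, out_shape = NULL, out_voxel = NULL,
                            chunks = c(2, 2, 2), order = 1, grid_step = 0) {
  stopifnot(inherits(v, "clem_volume"), inherits(field, "tps_transform"))
  if (!order %in% c(0, 1, 3)) stop("order must be 0, 1 or 3")
  chunks <- as.integer(chunks)
  if (length(chunks) == 1L) chunks <- rep(chunks, 3L)
  geo <- out_geometry(v, out_shape, out_voxel)
  arr <- v$data
  if (grid_step > 1) {
    # coarse evaluation of the mapped coordinates, then separable linear
    # interpolation of each coordinate component to the full grid
    axes_coarse <- lapply(geo$shape, function(n)
      seq(0, by = grid_step, length.out = ceiling((n - 1) / grid_step) + 1L))
    pc <- grid_coords(axes_coarse[[1]], axes_coarse[[2]], axes_coarse[[3]])
    mapped <- tps_eval(field, pc)
    cshape <- vapply(axes_coarse, length, integer(1))
    comp <- lapply(1:3, function(j) {
      a <- array(mapped[, j], cshape)
      for (ax in 1:3) {
        coords <- (seq_len(geo$shape[ax]) - 1) / grid_step
        a <- apply_axis_matrix(a, resample_axis_matrix(cshape[ax], coords, "linear"), ax)
      }
      a
    })
    vals <- interp_volume(arr, cbind(as.vector(comp[[1]]), as.vector(comp[[2]]),
                                     as.vector(comp[[3]])), order = order)
    return(volume(array(vals, geo$shape), geo$voxel, channel = v$channel))
  }
  out <- array(0, geo$shape)
  splits <- lapply(1:3, function(ax) {
    n <- geo$shape[ax]
    k <- min(chunks[ax], n)
    if (k == 1L) list(0:(n - 1))
    else split(0:(n - 1), cut(0:(n - 1), k, labels = FALSE))
  })
  for (zs in splits[[1]]) for (ys in splits[[2]]) for (xs in splits[[3]]) {
    p <- grid_coords(zs, ys, xs)
    vals <- interp_volume(arr, tps_eval(field, p), order = order)
    out[zs + 1L, ys + 1L, xs + 1L] <-
      array(vals, c(length(zs), length(ys), length(xs)))
  }
  volume(out, geo$voxel, channel = v$channel)
}

#' Resample a volume onto the grid of an EM volume
#'
#' The output shares the EM grid geometry exactly; each EM voxel center is
#' mapped to its physical position in nm and the input volume is sampled
#' there (both grids share the coordinate origin).
#'
#' @param v input `clem_volume` with physical voxel sizes.
#' @param em reference `clem_volume` or `clem_labels` whose geometry to adopt.
#' @param order interpolation order 0 or 1 (default 1).
#' @return `clem_volume` on the EM grid.
#' @export
resample_to_em <- function(v, em, order = 1) {
  stopifnot(inherits(v, "clem_volume"))
  if (is.null(v$voxel_size) || is.null(em$voxel_size))
    stop("both volumes need voxel sizes")
  if (!order %in% c(0, 1)) stop("order must be 0 or 1 for grid resampling")
  d_em <- dim(vol_data(em))
  arr <- v$data
  mode <- if (order == 0) "nearest" else "linear"
  identical_grid <- identical(dim(arr), d_em) &&
    all(abs(v$voxel_size - em$voxel_size) < 1e-9)
  if (identical_grid) return(volume(arr, em$voxel_size, channel = v$channel))
  for (ax in 1:3) {
    coords <- (seq_len(d_em[ax]) - 1) * em$voxel_size[ax] / v$voxel_size[ax]
    K <- resample_axis_matrix(dim(arr)[ax], coords, mode)
    arr <- apply_axis_matrix(arr, K, ax)
  }
  volume(arr, em$voxel_size, channel = v$channel)
}
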