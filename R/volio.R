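# Containers and I/O shared by all pipeline stages.

#' Intensity volume
#'
#' A 3D scalar grid indexed `(z, y, x)` with a per-axis voxel size in
#' nanometres. Voxel centers sit at integer coordinates `0 .. n-1` along each
#' axis, so the physical position of voxel `(i,j,k)` is
#' `(i,j,k) * voxel_size` nm.
#'
#' @param data 3D numeric array, indexed `(z, y, x)`; must be finite.
#' @param voxel_size numeric length-3 `(z, y, x)` voxel edge lengths in nm
#'   (a scalar is recycled); all strictly positive.
#' @param channel free-text channel name.
#' @return An object of class `clem_volume` with fields `data`, `voxel_size`,
#'   `channel`.
#' @export
volume <- function(data, voxel_size, channel = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array (z, y, x)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel sizes must be strictly positive (z, y, x) in nm")
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume data must be finite")
  structure(list(data = data, voxel_size = voxel_size, channel = channel),
            class = "clem_volume")
}

#' Label (instance segmentation) volume
#'
#' A 3D non-negative integer grid sharing the [volume()] geometry;
#' 0 is background. Instance ids need not be contiguous.
#'
#' @param labels 3D array of non-negative integers, indexed `(z, y, x)`.
#' @param voxel_size `(z, y, x)` voxel size in nm, strictly positive.
#' @return An object of class `clem_labels` with fields `labels`, `voxel_size`.
#' @export
label_volume <- function(labels, voxel_size) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array (z, y, x)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel sizes must be strictly positive (z, y, x) in nm")
  if (anyNA(labels) || any(labels < 0))
    stop("labels must be non-negative and finite")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_size = voxel_size),
            class = "clem_labels")
}

#' @export
print.clem_volume <- function(x, ...) {
  cat(sprintf("<clem_volume> %s  shape (z,y,x) = %s  voxel (nm) = %s  range [%.4g, %.4g]\n",
              if (nzchar(x$channel)) x$channel else "(unnamed)",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.clem_labels <- function(x, ...) {
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("<clem_labels> shape (z,y,x) = %s  voxel (nm) = %s  %d instance(s)\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              length(ids)))
  invisible(x)
}

is_labels <- function(x) inherits(x, "clem_labels")
vol_data <- function(x) if (is_labels(x)) x$labels else x$data

#' Read a multi-page TIFF stack as a volume or label volume
#'
#' Page order maps to z; each page is read as a `(y, x)` matrix.
#'
#' @param path path to a multi-page TIFF (8/16-bit integer or 32-bit float).
#' @param voxel_size `(z, y, x)` voxel size in nm, strictly positive.
#' @param kind `"intensity"` returns a [volume()]; `"labels"` returns a
#'   [label_volume()] with integer sample values taken as instance ids.
#' @param channel channel name attached to intensity volumes.
#' @return A `clem_volume` or `clem_labels`.
#' @export
read_stack <- function(path, voxel_size, kind = c("intensity", "labels"),
                       channel = "") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (kind == "labels"))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("volume must have >=2 z-slices")
  if (length(dim(pages[[1]])) != 2L)
    stop("stack pages must be single-channel 2D images")
  arr <- aperm(simplify2array(pages), c(3, 1, 2))
  if (kind == "labels") label_volume(arr, voxel_size)
  else volume(arr, voxel_size, channel = channel)
}

#' Write a volume or label volume as a multi-page TIFF
#'
#' Intensity volumes are stored as 32-bit float and must lie in `[0, 1]`
#' (pipeline intensities are min-max normalized); label volumes are stored
#' as 16-bit integers (instance ids must be < 65536).
#'
#' @param v a `clem_volume` or `clem_labels`.
#' @param path output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(v, path) {
  if (is_labels(v)) {
    if (max(v$labels) > 65535L) stop("label ids must be < 65536 for TIFF export")
    pages <- lapply(seq_len(dim(v$labels)[1]),
                    function(z) v$labels[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    if (min(v$data) < 0 || max(v$data) > 1)
      stop("intensity volumes must lie in [0, 1] for TIFF export; normalize first")
    pages <- lapply(seq_len(dim(v$data)[1]), function(z) v$data[z, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

# Read a label TIFF written by write_stack (16-bit): recover integer ids.
#' @rdname read_stack
#' @export
read_label_stack <- function(path, voxel_size) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("volume must have >=2 z-slices")
  arr <- aperm(simplify2array(pages), c(3, 1, 2))
  label_volume(arr, voxel_size)
}

# per-axis weight matrix mapping input samples (centers 0..n_in-1) to output
# positions `coords` (in input index units); linear or nearest
resample_axis_matrix <- function(n_in, coords, mode) {
  K <- matrix(0, length(coords), n_in)
  cc <- pmin(pmax(coords, 0), n_in - 1)
  if (n_in == 1L) { K[, 1] <- 1; return(K) }
  if (mode == "nearest") {
    idx <- pmin(floor(cc + 0.5), n_in - 1)
    K[cbind(seq_along(cc), idx + 1)] <- 1
  } else {
    lo <- pmax(pmin(floor(cc), n_in - 2), 0)
    f <- cc - lo
    K[cbind(seq_along(cc), lo + 1)] <- K[cbind(seq_along(cc), lo + 1)] + 1 - f
    K[cbind(seq_along(cc), lo + 2)] <- K[cbind(seq_along(cc), lo + 2)] + f
  }
  K
}

#' Resample a volume to isotropic voxels
#'
#' The output grid has voxel size `(t, t, t)` nm with
#' `shape = round(extent_nm / target_nm)` per axis (extent = voxel count x
#' voxel size), preserving the physical extent within one voxel per axis.
#' Intensities are linearly interpolated; label volumes must use
#' nearest-neighbor so the label set is preserved.
#'
#' @param v a `clem_volume` or `clem_labels`.
#' @param target_nm target isotropic voxel size in nm (> 0).
#' @param mode `"linear"` (volumes) or `"nearest"` (mandatory for labels).
#' @return Same kind as `v`, on the isotropic grid.
#' @export
resample_isotropic <- function(v, target_nm, mode = if (is_labels(v)) "nearest" else "linear") {
  mode <- match.arg(mode, c("linear", "nearest"))
  if (!is.numeric(target_nm) || length(target_nm) != 1L || target_nm <= 0)
    stop("target_nm must be a positive scalar")
  if (is_labels(v) && mode == "linear")
    stop("linear interpolation is not allowed for label volumes; use mode = 'nearest'")
  arr <- vol_data(v) * 1.0
  d <- dim(arr)
  out_n <- pmax(1L, as.integer(round(d * v$voxel_size / target_nm)))
  for (ax in 1:3) {
    if (out_n[ax] == d[ax] && abs(v$voxel_size[ax] - target_nm) < 1e-12) next
    coords <- (seq_len(out_n[ax]) - 1) * target_nm / v$voxel_size[ax]
    K <- resample_axis_matrix(d[ax], coords, mode)
    arr <- apply_axis_matrix(arr, K, ax)
  }
  if (is_labels(v)) label_volume(array(as.integer(round(arr)), dim(arr)), rep(target_nm, 3))
  else volume(arr, rep(target_nm, 3), channel = v$channel)
}

#' Bin a volume by block averaging
#'
#' Each output voxel is the mean of an `fz x fy x fx` block of input voxels;
#' the voxel size is multiplied by the factors. Trailing partial blocks are
#' averaged over their actual size.
#'
#' @param v a `clem_volume`.
#' @param factors integer `(z, y, x)` binning factors, each >= 1 and no larger
#'   than the corresponding axis length.
#' @return Binned `clem_volume`.
#' @export
bin_volume <- function(v, factors) {
  stopifnot(inherits(v, "clem_volume"))
  factors <- as.integer(factors)
  if (length(factors) == 1L) factors <- rep(factors, 3L)
  d <- dim(v$data)
  if (any(factors < 1L)) stop("binning factors must be >= 1")
  if (any(factors > d)) stop("binning factor exceeds axis length")
  arr <- v$data
  for (ax in 1:3) {
    f <- factors[ax]
    if (f == 1L) next
    n <- dim(arr)[ax]
    n_out <- as.integer(ceiling(n / f))
    K <- matrix(0, n_out, n)
    for (i in seq_len(n_out)) {
      j <- ((i - 1L) * f + 1L):min(i * f, n)
      K[i, j] <- 1 / length(j)
    }
    arr <- apply_axis_matrix(arr, K, ax)
  }
  volume(arr, v$voxel_size * factors, channel = v$channel)
}

# R wrapper over the compiled 3D connected-components labeling
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- cc_label_3d(as.logical(mask), as.integer(d), as.integer(connectivity))
  array(lab, d)
}

#' Merge segmentation masks by summation
#'
#' Input masks are summed, binarized (any positive vote = foreground) and the
#' union is relabeled by 26-connected components, so the output foreground is
#' the voxelwise union of the inputs.
#'
#' @param masks list of `clem_labels` with identical geometry.
#' @return A `clem_labels` with relabeled instances.
#' @export
merge_masks_by_sum <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  d <- dim(masks[[1]]$labels)
  vs <- masks[[1]]$voxel_size
  for (m in masks) {
    if (!is_labels(m)) stop("all inputs must be label volumes")
    if (!identical(dim(m$labels), d) || any(abs(m$voxel_size - vs) > 1e-9))
      stop("geometry mismatch between masks")
  }
  s <- Reduce(`+`, lapply(masks, function(m) (m$labels > 0L) * 1L))
  lab <- label_components(s > 0L, 26L)
  label_volume(lab, vs)
}

#' Point cloud
#'
#' An ordered `N x 3` set of `(z, y, x)` coordinates with a declared
#' coordinate space: `"pixel"` (an isotropic grid whose step in nm is
#' `step_nm`) or `"nm"`.
#'
#' @param points numeric `N x 3` matrix, columns `(z, y, x)`; finite.
#' @param space `"pixel"` or `"nm"`.
#' @param step_nm grid step in nm when `space = "pixel"`.
#' @param source free text (`"fm"`, `"em"`, ...).
#' @return An object of class `clem_points`.
#' @export
point_cloud <- function(points, space = c("pixel", "nm"), step_nm = NA_real_,
                        source = "") {
  space <- match.arg(space)
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0L, 3L)
  if (ncol(points) != 3L) stop("points must be an N x 3 matrix (z, y, x)")
  if (nrow(points) > 0L && any(!is.finite(points))) stop("point coordinates must be finite")
  colnames(points) <- c("z", "y", "x")
  structure(list(points = points, space = space, step_nm = step_nm,
                 source = source), class = "clem_points")
}

#' @export
print.clem_points <- function(x, ...) {
  cat(sprintf("<clem_points> %d point(s), space = %s%s%s\n", nrow(x$points), x$space,
              if (!is.na(x$step_nm)) sprintf(" (step %g nm)", x$step_nm) else "",
              if (nzchar(x$source)) paste0(", source = ", x$source) else ""))
  invisible(x)
}

as_points_matrix <- function(x) {
  if (inherits(x, "clem_points")) x$points else {
    m <- as.matrix(x)
    stopifnot(ncol(m) == 3L)
    m
  }
}

#' Write / read point clouds as CSV
#'
#' The CSV carries comment headers `# space=pixel|nm`, `# step_nm=...`,
#' `# source=...` followed by `z,y,x` columns; round trips are lossless to
#' better than 1e-9.
#'
#' @param pc a [point_cloud()].
#' @param path CSV path.
#' @return `write_point_cloud` returns `path` invisibly; `read_point_cloud`
#'   returns a `clem_points`.
#' @export
write_point_cloud <- function(pc, path) {
  stopifnot(inherits(pc, "clem_points"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# space=", pc$space),
               paste0("# step_nm=", format(pc$step_nm, digits = 17)),
               paste0("# source=", pc$source),
               "z,y,x"), con)
  if (nrow(pc$points) > 0L) {
    writeLines(apply(pc$points, 1L, function(r)
      paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = ",")), con)
  }
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(m) == 0L) return(NA_character_)
    sub(paste0("^#\\s*", key, "="), "", m[1])
  }
  space <- get_field("space")
  if (is.na(space) || !space %in% c("pixel", "nm"))
    stop("malformed point-cloud header: missing '# space=pixel|nm'")
  body <- lines[!grepl("^#", lines)]
  df <- read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("z", "y", "x") %in% names(df)))
    stop("point-cloud CSV must have z, y, x columns")
  step <- suppressWarnings(as.numeric(get_field("step_nm")))
  src <- get_field("source")
  point_cloud(as.matrix(df[, c("z", "y", "x")]), space = space,
              step_nm = step, source = if (is.na(src)) "" else src)
}

#' Write / read spatial transforms as JSON
#'
#' Serializes rigid, affine and thin-plate-spline transforms as tagged JSON
#' (`"kind": "rigid" | "affine" | "tps"`); round trips preserve all
#' parameters to full double precision.
#'
#' @param tr a transform from [rigid_transform()], [affine_transform()] or
#'   [tps_fit()].
#' @param path JSON path.
#' @export
write_transform <- function(tr, path) {
  obj <- if (inherits(tr, "rigid_transform")) {
    list(kind = "rigid", scale = tr$scale, rotation = tr$rotation,
         translation = tr$translation, units = tr$units, step_nm = tr$step_nm)
  } else if (inherits(tr, "affine_transform")) {
    list(kind = "affine", matrix = tr$matrix, translation = tr$translation,
         units = tr$units, step_nm = tr$step_nm)
  } else if (inherits(tr, "tps_transform")) {
    list(kind = "tps", control = tr$control, affine = tr$affine,
         translation = tr$translation, weights = tr$weights)
  } else stop("unsupported transform type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) matrix(as.numeric(t(m)), nrow = nrow(m), byrow = TRUE)
  if (is.null(obj$kind)) stop("malformed transform JSON: missing 'kind'")
  if (obj$kind == "rigid") {
    rigid_transform(rotation = obj$rotation, translation = as.numeric(obj$translation),
                    scale = obj$scale, units = obj$units,
                    step_nm = if (is.null(obj$step_nm)) NA_real_ else obj$step_nm)
  } else if (obj$kind == "affine") {
    affine_transform(matrix = obj$matrix, translation = as.numeric(obj$translation),
                     units = obj$units,
                     step_nm = if (is.null(obj$step_nm)) NA_real_ else obj$step_nm)
  } else if (obj$kind == "tps") {
    new_tps_transform(control = obj$control, affine = obj$affine,
                      translation = as.numeric(obj$translation), weights = obj$weights)
  } else stop("unknown transform kind: ", obj$kind)
}
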