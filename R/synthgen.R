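# Synthetic paired FM/EM fixtures with known ground truth. The generator
# emulates the benchmark layout: ellipsoidal landmark organelles
# (mitochondria) scattered through an ellipsoidal cell, an EM label volume
# on a near-isotropic grid, an FM stack on its own anisotropic grid produced
# by a known rigid transform plus anisotropic PSF blur, depth-dependent
# attenuation and noise, and spherical 0.3-1 um targets for evaluation.

#' Fixture specification
#'
#' Defaults define the standard study conditions: an EM grid of
#' `(80, 304, 304)` voxels at 25 nm (a flat, adherent-cell-like field),
#' 40 tubule-like mitochondria with full axis lengths 800-1200 nm (major)
#' by 400-550 nm (minor) separated by at least 100 nm, five spherical
#' targets of 300-1000 nm diameter, a rigid ground truth of 10 degrees
#' rotation about z plus a 15 px translation, an FM grid of `(80, 40, 40)`
#' nm voxels, a Gaussian PSF of sigma `(149, 51, 51)` nm (the stated
#' 350 nm axial / 120 nm lateral resolution read as FWHM), 0.5 %/slice
#' exponential depth attenuation and Gaussian noise (sd 0.02).
#'
#' @param seed RNG seed; all fixture randomness derives from it.
#' @param shape EM `(z, y, x)` voxel counts.
#' @param em_voxel_nm EM isotropic voxel size in nm.
#' @param n_mito number of landmark instances (>= 4).
#' @param mito_major_nm,mito_minor_nm full axis-length ranges in nm.
#' @param gap_nm minimum separation between instances in nm.
#' @param n_targets number of spherical target structures.
#' @param target_diam_nm target diameter range in nm.
#' @param rotation_deg ground-truth rotation about the z axis, degrees.
#' @param translation_px ground-truth extra translation in EM voxels.
#' @param fm_voxel_nm FM `(z, y, x)` voxel size in nm.
#' @param fm_margin_nm FM field-of-view margin around the EM extent.
#' @param psf_sigma_nm FM point-spread sigma `(z, y, x)` in nm.
#' @param attenuation per-slice intensity decay rate of the FM signal.
#' @param noise_sd Gaussian noise sd on the unit-amplitude FM signal.
#' @param poisson also apply Poisson resampling of the FM signal?
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, shape = c(80L, 304L, 304L), em_voxel_nm = 25,
                         n_mito = 40L, mito_major_nm = c(800, 1200),
                         mito_minor_nm = c(400, 550), gap_nm = 100,
                         n_targets = 5L, target_diam_nm = c(300, 1000),
                         rotation_deg = 10, translation_px = c(2, 10, 11),
                         fm_voxel_nm = c(80, 40, 40), fm_margin_nm = 600,
                         psf_sigma_nm = c(149, 51, 51), attenuation = 0.005,
                         noise_sd = 0.02, poisson = FALSE) {
  spec <- list(seed = seed, shape = as.integer(shape), em_voxel_nm = em_voxel_nm,
               n_mito = as.integer(n_mito), mito_major_nm = mito_major_nm,
               mito_minor_nm = mito_minor_nm, gap_nm = gap_nm,
               n_targets = as.integer(n_targets), target_diam_nm = target_diam_nm,
               rotation_deg = rotation_deg, translation_px = translation_px,
               fm_voxel_nm = fm_voxel_nm, fm_margin_nm = fm_margin_nm,
               psf_sigma_nm = psf_sigma_nm, attenuation = attenuation,
               noise_sd = noise_sd, poisson = poisson)
  stopifnot(spec$n_mito >= 4L, all(spec$shape > 0), em_voxel_nm > 0,
            all(diff(mito_major_nm) >= 0), all(spec$fm_voxel_nm > 0),
            all(spec$psf_sigma_nm > 0), spec$gap_nm >= 0)
  class(spec) <- "fixture_spec"
  spec
}

# uniformly random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# linear indices of voxels inside a rotated ellipsoid (semi-axes in voxels)
ellipsoid_indices <- function(d, center, axes, R) {
  rmax <- max(axes)
  lo <- pmax(0, floor(center - rmax))
  hi <- pmin(d - 1, ceiling(center + rmax))
  if (any(hi < lo)) return(integer(0))
  p <- grid_coords(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
  q <- sweep(p, 2L, center) %*% R          # world -> ellipsoid frame
  inside <- rowSums(sweep(q, 2L, axes, "/")^2) <= 1
  p <- p[inside, , drop = FALSE]
  as.integer(p[, 1] + 1 + d[1] * p[, 2] + d[1] * d[2] * p[, 3])
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(th), -sin(th),
           0, sin(th), cos(th)), 3, 3, byrow = TRUE)
}

#' Generate a paired FM/EM fixture with known ground truth
#'
#' Places non-overlapping ellipsoidal landmark instances and spherical
#' targets inside an ellipsoidal cell on the EM grid, then renders the FM
#' channels on their own anisotropic grid by pulling the EM masks through
#' the inverse of the ground-truth rigid transform, blurring with the
#' anisotropic PSF, attenuating with depth and adding noise. All randomness
#' derives from `spec$seed`; the same spec reproduces the fixture
#' bit-for-bit.
#'
#' @param spec a [fixture_spec()].
#' @return A list of class `clem_fixture`: `em_labels`, `em_targets`,
#'   `em_intensity` (EM grid), `fm_landmark`, `fm_target` (FM grid), `truth`
#'   (a nm-space [rigid_transform()] mapping FM to EM coordinates),
#'   `landmark_pairs` (paired nm [point_cloud()]s at the instance centers),
#'   `target_truth` (data frame of target centers and radii), `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    d <- spec$shape
    vx <- spec$em_voxel_nm
    c0 <- (d - 1) / 2
    cell_axes <- 0.45 * d
    occ <- array(FALSE, d)
    labels <- array(0L, d)
    centers <- matrix(0, spec$n_mito, 3)
    gap_vox <- spec$gap_nm / vx

    place_one <- function(axes_vox, avoid, max_tries = 2000L) {
      rmax <- max(axes_vox)
      for (try in seq_len(max_tries)) {
        R <- random_rotation()
        cen <- runif(3, rmax, d - 1 - rmax)
        if (sum(((cen - c0) / pmax(cell_axes - rmax, 1))^2) > 1) next
        idx_gap <- ellipsoid_indices(d, cen, axes_vox + gap_vox, R)
        if (any(avoid[idx_gap])) next
        return(list(center = cen, axes = axes_vox, R = R,
                    idx = ellipsoid_indices(d, cen, axes_vox, R)))
      }
      stop("could not place instance after ", max_tries,
           " tries: spec is overcrowded")
    }

    # targets are placed first: the largest spheres need the largest pockets
    targets <- array(0L, d)
    target_rows <- vector("list", spec$n_targets)
    for (i in seq_len(spec$n_targets)) {
      r <- runif(1, spec$target_diam_nm[1], spec$target_diam_nm[2]) / 2 / vx
      pl <- place_one(rep(r, 3), occ)
      targets[pl$idx] <- i
      occ[pl$idx] <- TRUE
      target_rows[[i]] <- data.frame(id = i,
                                     z_nm = pl$center[1] * vx,
                                     y_nm = pl$center[2] * vx,
                                     x_nm = pl$center[3] * vx,
                                     radius_nm = r * vx)
    }
    target_truth <- do.call(rbind, target_rows)

    # draw all landmark sizes first, then place the largest first: packing
    # succeeds far more often when big instances claim space early
    mito_axes <- lapply(seq_len(spec$n_mito), function(i)
      c(runif(1, spec$mito_major_nm[1], spec$mito_major_nm[2]) / 2 / vx,
        runif(2, spec$mito_minor_nm[1], spec$mito_minor_nm[2]) / 2 / vx))
    for (i in order(vapply(mito_axes, prod, numeric(1)), decreasing = TRUE)) {
      pl <- place_one(mito_axes[[i]], occ)
      labels[pl$idx] <- i
      occ[pl$idx] <- TRUE
      centers[i, ] <- pl$center
    }

    em_int <- 0.25 + 0.5 * (labels > 0L) + 0.15 * (targets > 0L) +
      array(rnorm(prod(d), 0, 0.05), d)
    em_int <- pmin(pmax(em_int, 0), 1)

    # ground truth: FM (nm) -> EM (nm), rotation about the volume center
    Rg <- rot_z(spec$rotation_deg)
    t_extra <- spec$translation_px * vx
    c_em <- (d - 1) / 2 * vx
    fm_extent <- d * vx + 2 * spec$fm_margin_nm
    fd <- as.integer(ceiling(fm_extent / spec$fm_voxel_nm))
    c_fm <- (fd - 1) / 2 * spec$fm_voxel_nm
    truth <- rigid_transform(rotation = Rg,
                             translation = as.numeric(c_em + t_extra - Rg %*% c_fm),
                             scale = 1, units = "nm", step_nm = NA_real_)

    render_fm <- function(mask) {
      p_nm <- sweep(grid_coords(0:(fd[1] - 1), 0:(fd[2] - 1), 0:(fd[3] - 1)),
                    2L, spec$fm_voxel_nm, "*")
      q_idx <- sweep(transform_points_matrix(truth, p_nm), 2L, vx, "/")
      ch <- array(interp_volume((mask > 0L) * 1.0, q_idx, order = 1), fd)
      ch <- gaussian_blur3(ch, spec$psf_sigma_nm / spec$fm_voxel_nm)
      decay <- exp(-spec$attenuation * (0:(fd[1] - 1)))
      ch <- ch * array(rep(decay, times = fd[2] * fd[3]), fd)
      if (spec$poisson) {
        counts <- 200
        ch <- array(stats::rpois(prod(fd), ch * counts) / counts, fd)
      }
      ch <- ch + array(rnorm(prod(fd), 0, spec$noise_sd), fd)
      volume(pmax(ch, 0), spec$fm_voxel_nm)
    }
    fm_landmark <- render_fm(labels)
    fm_landmark$channel <- "landmark"
    fm_target <- render_fm(targets)
    fm_target$channel <- "target"

    centers_nm <- sweep(centers, 2L, vx, "*")
    inv <- invert_transform(truth)
    moving <- transform_points_matrix(inv, centers_nm)

    structure(list(
      em_labels = label_volume(labels, vx),
      em_targets = label_volume(targets, vx),
      em_intensity = volume(em_int, vx, channel = "em"),
      fm_landmark = fm_landmark,
      fm_target = fm_target,
      truth = truth,
      landmark_pairs = list(
        moving = point_cloud(moving, space = "nm", source = "fm"),
        fixed = point_cloud(centers_nm, space = "nm", source = "em")),
      target_truth = target_truth,
      spec = spec), class = "clem_fixture")
  })
}

#' Degrade a fixture by removing EM instances
#'
#' Wraps [ablate_instances()] on the EM label volume, leaving the FM
#' channels untouched, to emulate missed segmentations.
#'
#' @param fx a `clem_fixture`.
#' @param missing_fraction fraction of instances to remove, in `[0, 1)`.
#' @param mode `"random"`, `"peripheral"` or `"central"`.
#' @param seed RNG seed for random removal.
#' @return The degraded fixture.
#' @export
degrade_fixture <- function(fx, missing_fraction, mode = "random", seed = 1L) {
  stopifnot(inherits(fx, "clem_fixture"))
  fx$em_labels <- ablate_instances(fx$em_labels, missing_fraction, mode, seed)
  fx
}

#' @export
print.clem_fixture <- function(x, ...) {
  cat(sprintf(paste0("<clem_fixture> EM %s @ %g nm (%d instances, %d targets); ",
                     "FM %s @ (%s) nm; truth: %.3g deg rotation, |t| = %.3g px\n"),
              paste(dim(x$em_labels$labels), collapse = "x"), x$spec$em_voxel_nm,
              max(x$em_labels$labels), x$spec$n_targets,
              paste(dim(x$fm_landmark$data), collapse = "x"),
              paste(x$spec$fm_voxel_nm, collapse = ","),
              x$spec$rotation_deg,
              sqrt(sum(x$spec$translation_px^2)))
  )
  invisible(x)
}
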