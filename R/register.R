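# Coherent point drift registration (rigid / affine / nonrigid), implemented
# from the Gaussian-mixture EM formulation. The source cloud parametrizes the
# mixture centroids; the target cloud is the data. Each EM iteration computes
# soft correspondences (E-step) and the closed-form transform and variance
# update (M-step), so the negative log-likelihood is non-increasing.

#' Rigid transform
#'
#' `T(p) = scale * R p + t` with `R` a proper rotation.
#'
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation length-3 vector `(z, y, x)`.
#' @param scale positive scalar.
#' @param units `"pixel"` (isotropic grid) or `"nm"`.
#' @param step_nm grid step in nm when `units = "pixel"`.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1, units = "pixel", step_nm = NA_real_) {
  rotation <- matrix(as.numeric(as.matrix(rotation)), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L, is.numeric(scale), scale > 0)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) <= 0)
    stop("rotation must be orthonormal with det +1")
  structure(list(rotation = rotation, translation = translation, scale = scale,
                 units = units, step_nm = step_nm), class = "rigid_transform")
}

#' Affine transform
#'
#' `T(p) = A p + t` with invertible `A`.
#'
#' @param matrix 3x3 invertible matrix.
#' @param translation length-3 vector `(z, y, x)`.
#' @inheritParams rigid_transform
#' @return Object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0),
                             units = "pixel", step_nm = NA_real_) {
  A <- base::matrix(as.numeric(as.matrix(matrix)), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (abs(det(A)) <= 1e-12) stop("affine matrix must be invertible")
  structure(list(matrix = A, translation = translation,
                 units = units, step_nm = step_nm), class = "affine_transform")
}

# Gaussian-kernel displacement field fitted by nonrigid CPD
new_cpd_field <- function(anchors, weights, beta, shift) {
  structure(list(anchors = anchors, weights = weights, beta = beta,
                 shift = shift, units = "pixel", step_nm = NA_real_),
            class = "cpd_field")
}

# forward-map an N x 3 coordinate matrix through any supported transform
transform_points_matrix <- function(tr, P) {
  if (inherits(tr, "rigid_transform")) {
    sweep(P %*% t(tr$rotation) * tr$scale, 2L, tr$translation, "+")
  } else if (inherits(tr, "affine_transform")) {
    sweep(P %*% t(tr$matrix), 2L, tr$translation, "+")
  } else if (inherits(tr, "cpd_field")) {
    G <- gauss_gram(P, tr$anchors, tr$beta)
    P + G %*% tr$weights + matrix(tr$shift, nrow(P), 3L, byrow = TRUE)
  } else if (inherits(tr, "tps_transform")) {
    tps_eval(tr, P)
  } else stop("unsupported transform type")
}

#' Apply a spatial transform to a point cloud
#'
#' @param pc a [point_cloud()] or bare `N x 3` matrix.
#' @param tr a rigid, affine, thin-plate-spline or CPD displacement-field
#'   transform.
#' @return Same kind as `pc`, with transformed coordinates. Transform and
#'   cloud must agree on units (`pixel` vs `nm`).
#' @export
apply_transform <- function(pc, tr) {
  if (inherits(pc, "clem_points")) {
    tru <- if (is.null(tr$units)) pc$space else tr$units
    if (!identical(tru, pc$space))
      stop("space mismatch: cloud is in '", pc$space, "', transform in '", tru, "'")
    point_cloud(transform_points_matrix(tr, pc$points), space = pc$space,
                step_nm = pc$step_nm, source = pc$source)
  } else {
    transform_points_matrix(tr, as_points_matrix(pc))
  }
}

#' Invert a rigid or affine transform
#'
#' @param tr a `rigid_transform` or `affine_transform`.
#' @return The inverse transform of the same class.
#' @export
invert_transform <- function(tr) {
  if (inherits(tr, "rigid_transform")) {
    Rt <- t(tr$rotation)
    rigid_transform(rotation = Rt,
                    translation = as.numeric(-Rt %*% tr$translation) / tr$scale,
                    scale = 1 / tr$scale, units = tr$units, step_nm = tr$step_nm)
  } else if (inherits(tr, "affine_transform")) {
    Ai <- solve(tr$matrix)
    affine_transform(matrix = Ai, translation = as.numeric(-Ai %*% tr$translation),
                     units = tr$units, step_nm = tr$step_nm)
  } else stop("only rigid and affine transforms have closed-form inverses")
}

#' Convert a pixel-space transform to physical units
#'
#' The rotation/matrix part is unit-free; only the translation is scaled by
#' the isotropic grid step. `to_pixel` is the exact inverse conversion.
#'
#' @param tr a `rigid_transform` or `affine_transform` in pixel units.
#' @param grid_step_nm isotropic grid step in nm.
#' @return The same transform expressed in nm (or pixels for `to_pixel`).
#' @export
to_physical <- function(tr, grid_step_nm) {
  stopifnot(is.numeric(grid_step_nm), length(grid_step_nm) == 1L, grid_step_nm > 0)
  if (!identical(tr$units, "pixel")) stop("transform is not in pixel units")
  tr$translation <- tr$translation * grid_step_nm
  tr$units <- "nm"
  tr$step_nm <- grid_step_nm
  tr
}

#' @rdname to_physical
#' @export
to_pixel <- function(tr, grid_step_nm = tr$step_nm) {
  stopifnot(is.numeric(grid_step_nm), length(grid_step_nm) == 1L, grid_step_nm > 0)
  if (!identical(tr$units, "nm")) stop("transform is not in nm units")
  tr$translation <- tr$translation / grid_step_nm
  tr$units <- "pixel"
  tr$step_nm <- grid_step_nm
  tr
}

# squared-distance matrix between row sets (M x 3, N x 3)
dist2_matrix <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d2
}

gauss_gram <- function(A, B, beta) exp(-dist2_matrix(A, B) / (2 * beta^2))

#' Coherent point drift registration
#'
#' Fits a transform mapping `source` onto `target` by expectation-
#' maximization over a Gaussian mixture whose centroids are the transformed
#' source points. `type = "rigid"` estimates rotation (via SVD of the
#' weighted cross-covariance), optional isotropic scale and translation;
#' `"affine"` a general linear map; `"nonrigid"` a smooth Gaussian-kernel
#' displacement field with stiffness `lambda` and kernel bandwidth `beta`
#' (run a rigid fit first for a rough pre-alignment). Clouds are centered
#' internally for conditioning; the returned transform acts in the original
#' coordinates.
#'
#' @param source,target [point_cloud()]s or `N x 3` matrices in a common
#'   space; at least 3 non-collinear points each.
#' @param type transform family.
#' @param max_iter maximum EM iterations (default 50).
#' @param w expected outlier fraction in `[0, 1)`.
#' @param tol convergence tolerance on the residual-variance change.
#' @param scale estimate an isotropic scale factor (rigid only)? With both
#'   clouds on a common nm grid the fitted scale should be about 1.
#' @param beta Gaussian kernel bandwidth (nonrigid), in cloud units.
#' @param lambda regularization weight (nonrigid); larger is stiffer, and
#'   `lambda -> Inf` approaches zero displacement.
#' @return Object of class `cpd_fit` with elements `transform`, `iterations`,
#'   `sigma2_trace`, `nll_trace`, `converged`, `w`, `type`, `sigma2`.
#' @export
cpd <- function(source, target, type = c("rigid", "affine", "nonrigid"),
                max_iter = 50L, w = 0, tol = 1e-6, scale = TRUE,
                beta = 2, lambda = 2) {
  type <- match.arg(type)
  Y0 <- as_points_matrix(source)   # moving (mixture centroids)
  X0 <- as_points_matrix(target)   # data
  if (inherits(source, "clem_points") && inherits(target, "clem_points") &&
      !identical(source$space, target$space))
    stop("source and target clouds are in different spaces")
  if (any(!is.finite(Y0)) || any(!is.finite(X0))) stop("non-finite input coordinates")
  M <- nrow(Y0); N <- nrow(X0); D <- 3L
  if (M < 3L || N < 3L) stop("need at least 3 points in each cloud")
  if (w < 0 || w >= 1) stop("w must be in [0, 1)")
  ybar <- colMeans(Y0); xbar <- colMeans(X0)
  Ys <- sweep(Y0, 2L, ybar); Xs <- sweep(X0, 2L, xbar)
  if (svd(Ys)$d[2] < 1e-9 * max(1, svd(Ys)$d[1]) ||
      svd(Xs)$d[2] < 1e-9 * max(1, svd(Xs)$d[1]))
    stop("degenerate (collinear) point geometry")

  sigma2 <- (N * sum(Ys^2) + M * sum(Xs^2)) / (D * M * N)
  TY <- Ys
  G <- NULL; W <- NULL
  if (type == "nonrigid") {
    if (beta <= 0 || lambda <= 0) stop("beta and lambda must be positive")
    G <- gauss_gram(Ys, Ys, beta)
    W <- matrix(0, M, D)
  }
  R_cur <- diag(D); s_cur <- 1; t_cur <- numeric(D); B_cur <- diag(D)
  sigma2_trace <- numeric(0); nll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E-step
    d2 <- dist2_matrix(TY, Xs)
    K <- exp(-d2 / (2 * sigma2))
    cs <- colSums(K)
    c_out <- (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N
    denom <- cs + c_out + 1e-300
    nll <- -sum(log((1 - w) / (M * (2 * pi * sigma2)^(D / 2)) * cs + w / N + 1e-300))
    if (type == "nonrigid") nll <- nll + lambda / 2 * sum(W * (G %*% W))
    nll_trace <- c(nll_trace, nll)
    P <- sweep(K, 2L, denom, "/")
    P1 <- rowSums(P); Pt1 <- colSums(P); Np <- sum(P1)
    PX <- P %*% Xs
    # M-step
    if (type == "nonrigid") {
      LHS <- G * P1 + diag(lambda * sigma2, M)
      W <- solve(LHS, PX - P1 * Ys)
      TY <- Ys + G %*% W
      s2 <- (sum(Pt1 * rowSums(Xs^2)) - 2 * sum(PX * TY) +
             sum(P1 * rowSums(TY^2))) / (Np * D)
    } else {
      mu_x <- as.numeric(t(Xs) %*% Pt1) / Np
      mu_y <- as.numeric(t(Ys) %*% P1) / Np
      Xh_ss <- sum(Pt1 * rowSums(sweep(Xs, 2L, mu_x)^2))
      Yh <- sweep(Ys, 2L, mu_y)
      # weighted cross-covariance: sum_mn P_mn (x_n - mu_x)(y_m - mu_y)^T
      A <- t(PX - outer(P1, mu_x)) %*% Yh
      if (type == "rigid") {
        sv <- svd(A)
        Cm <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
        R_cur <- sv$u %*% Cm %*% t(sv$v)
        yh_ss <- sum(P1 * rowSums(Yh^2))
        s_cur <- if (scale) sum(A * R_cur) / yh_ss else 1
        t_cur <- mu_x - s_cur * as.numeric(R_cur %*% mu_y)
        TY <- sweep(Ys %*% t(R_cur) * s_cur, 2L, t_cur, "+")
        s2 <- if (scale) (Xh_ss - s_cur * sum(A * R_cur)) / (Np * D)
              else (Xh_ss - 2 * sum(A * R_cur) + yh_ss) / (Np * D)
      } else {
        C2 <- t(Yh) %*% (Yh * P1)
        B_cur <- A %*% solve(C2)
        t_cur <- mu_x - as.numeric(B_cur %*% mu_y)
        TY <- sweep(Ys %*% t(B_cur), 2L, t_cur, "+")
        s2 <- (Xh_ss - sum(A * B_cur)) / (Np * D)
      }
    }
    if (!is.finite(s2)) s2 <- sigma2
    s2 <- max(s2, 1e-12)
    sigma2_prev <- sigma2
    sigma2 <- s2
    sigma2_trace <- c(sigma2_trace, sigma2)
    if (abs(sigma2_prev - sigma2) < tol) { converged <- TRUE; break }
  }

  transform <- if (type == "rigid") {
    rigid_transform(rotation = R_cur,
                    translation = t_cur + xbar - s_cur * as.numeric(R_cur %*% ybar),
                    scale = s_cur)
  } else if (type == "affine") {
    affine_transform(matrix = B_cur,
                     translation = t_cur + xbar - as.numeric(B_cur %*% ybar))
  } else {
    new_cpd_field(anchors = Y0, weights = W, beta = beta, shift = xbar - ybar)
  }
  if (inherits(source, "clem_points")) {
    transform$units <- source$space
    transform$step_nm <- source$step_nm
  }
  structure(list(transform = transform, iterations = iter,
                 sigma2_trace = sigma2_trace, nll_trace = nll_trace,
                 converged = converged, w = w, type = type,
                 sigma2 = sigma2, n_source = M, n_target = N,
                 beta = if (type == "nonrigid") beta else NA_real_,
                 lambda = if (type == "nonrigid") lambda else NA_real_),
            class = "cpd_fit")
}

#' @export
print.cpd_fit <- function(x, ...) {
  cat(sprintf("Coherent point drift (%s): %d -> %d points, %d iteration(s)%s\n",
              x$type, x$n_source, x$n_target, x$iterations,
              if (x$converged) ", converged" else ""))
  cat(sprintf("  residual variance sigma^2 = %.6g\n", x$sigma2))
  if (x$type == "rigid") {
    tr <- x$transform
    cat(sprintf("  scale = %.6g, |t| = %.4g, rotation angle = %.4g deg\n",
                tr$scale, sqrt(sum(tr$translation^2)),
                rotation_angle_deg(tr$rotation)))
  }
  invisible(x)
}

#' @export
summary.cpd_fit <- function(object, ...) {
  out <- list(fit = object,
              nll_drop = if (length(object$nll_trace) > 1)
                object$nll_trace[1] - object$nll_trace[length(object$nll_trace)]
              else 0)
  class(out) <- "summary.cpd_fit"
  out
}

#' @export
print.summary.cpd_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  objective decreased by %.6g over %d evaluation(s)\n",
              x$nll_drop, length(x$fit$nll_trace)))
  cat(sprintf("  sigma^2 trace: %s\n",
              paste(signif(utils::head(x$fit$sigma2_trace, 8), 4), collapse = " ")))
  invisible(x)
}

#' @export
coef.cpd_fit <- function(object, ...) {
  tr <- object$transform
  if (object$type == "rigid")
    list(scale = tr$scale, rotation = tr$rotation, translation = tr$translation)
  else if (object$type == "affine")
    list(matrix = tr$matrix, translation = tr$translation)
  else
    list(anchors = tr$anchors, weights = tr$weights, beta = tr$beta,
         shift = tr$shift)
}

#' @export
predict.cpd_fit <- function(object, newdata, ...) {
  apply_transform(newdata, object$transform)
}

#' @export
logLik.cpd_fit <- function(object, ...) {
  ll <- -object$nll_trace[length(object$nll_trace)]
  structure(ll, df = NA_integer_, class = "logLik")
}

#' @export
plot.cpd_fit <- function(x, ...) {
  graphics::plot(seq_along(x$sigma2_trace), x$sigma2_trace, type = "b",
                 log = "y", xlab = "EM iteration",
                 ylab = expression(sigma^2), ...)
  invisible(x)
}

#' Rotation angle of a rotation matrix, in degrees
#'
#' @param R 3x3 rotation matrix (or the relative rotation `R1 %*% t(R2)` for
#'   comparing two fits).
#' @return Angle in `[0, 180]` degrees.
#' @export
rotation_angle_deg <- function(R) {
  c_ang <- (sum(diag(R)) - 1) / 2
  acos(pmin(pmax(c_ang, -1), 1)) * 180 / pi
}
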