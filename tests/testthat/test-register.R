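test_that("rigid CPD self-registration returns the identity", {
  Y <- random_cloud(120, 41)
  fit <- cpd(Y, Y, type = "rigid")
  expect_lt(max(abs(fit$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(fit$transform$translation)), 1e-6)
  expect_equal(fit$transform$scale, 1, tolerance = 1e-6)
  expect_lt(fit$sigma2, 1e-6)
})

test_that("rigid CPD recovers a known rotation and translation", {
  Y <- random_cloud(200, 42)
  R <- rot_about_z(20)
  t0 <- c(5, -3, 2)
  X <- sweep(Y %*% t(R), 2L, t0, "+")
  fit <- cpd(Y, X, type = "rigid")
  expect_lt(rotation_angle_deg(fit$transform$rotation %*% t(R)), 0.1)
  expect_lt(sqrt(sum((fit$transform$translation - t0)^2)), 0.1)

  # random deletion of 40% of the source points (cloud sized so the
  # missing-data bias of the w = 0 mixture stays sub-degree)
  Yb <- random_cloud(500, 42)
  Xb <- sweep(Yb %*% t(R), 2L, t0, "+")
  set.seed(43)
  keep <- sample(500, 300)
  fit2 <- cpd(Yb[keep, ], Xb, type = "rigid")
  expect_lt(rotation_angle_deg(fit2$transform$rotation %*% t(R)), 1)
})

test_that("rigid CPD tolerates 5% jitter within the stated error bounds", {
  Y <- random_cloud(200, 44)
  R <- rot_about_z(20)
  t0 <- c(5, -3, 2)
  set.seed(45)
  # 5% relative jitter: sd = 5% of the cloud's per-axis standard deviation
  jit <- matrix(rnorm(600, 0, 0.05 * mean(apply(Y, 2, sd))), ncol = 3)
  X <- sweep(Y %*% t(R), 2L, t0, "+") + jit
  fit <- cpd(Y, X, type = "rigid")
  expect_lt(rotation_angle_deg(fit$transform$rotation %*% t(R)), 2)
  expect_lt(sqrt(sum((fit$transform$translation - t0)^2)), 1)
})

test_that("affine CPD recovers linear maps and reduces to rigid when apt", {
  Y <- random_cloud(200, 46)
  A <- matrix(c(1, 0.3, 0, 0, 1.1, 0, 0.1, 0, 0.9), 3, 3, byrow = TRUE)
  X <- sweep(Y %*% t(A), 2L, c(1, 2, 3), "+")
  fit <- cpd(Y, X, type = "affine")
  expect_lt(max(abs(fit$transform$matrix - A)), 1e-3)

  self <- cpd(Y, Y, type = "affine")
  expect_lt(max(abs(self$transform$matrix - diag(3))), 1e-6)

  R <- rot_about_z(25)
  Xr <- sweep(Y %*% t(R) * 1.2, 2L, c(2, 1, 0), "+")
  fr <- cpd(Y, Xr, type = "affine")
  M <- fr$transform$matrix
  expect_lt(max(abs(crossprod(M) - 1.2^2 * diag(3))), 1e-3)
})

test_that("nonrigid CPD recovers smooth deformations and stiffens with lambda", {
  Y <- random_cloud(80, 47, 0, 40)
  self <- cpd(Y, Y, type = "nonrigid", beta = 5, lambda = 2)
  expect_lt(max(abs(predict(self, Y) - Y)), 1e-3)

  X <- Y + 2 * sin(Y / 8)
  fit <- cpd(Y, X, type = "nonrigid", beta = 8, lambda = 0.5)
  resid <- sqrt(rowSums((predict(fit, Y) - X)^2))
  expect_lt(mean(resid), 0.5)

  stiff <- cpd(Y, X, type = "nonrigid", beta = 8, lambda = 1e9)
  disp <- predict(stiff, Y) - Y
  disp <- sweep(disp, 2L, colMeans(disp))  # the constant shift is unpenalized
  expect_lt(max(abs(disp)), 1e-3)
  expect_error(cpd(Y, X, type = "nonrigid", beta = -1), "beta")
})

test_that("transforms apply, invert and convert units exactly", {
  pc <- point_cloud(random_cloud(50, 48), space = "pixel", step_nm = 20)
  id <- rigid_transform()
  expect_equal(apply_transform(pc, id)$points, pc$points)

  tr <- rigid_transform(translation = c(1, 2, 3))
  expect_equal(apply_transform(pc, tr)$points, sweep(pc$points, 2L, c(1, 2, 3), "+"))

  rt <- rigid_transform(rotation = rot_about_z(33), translation = c(4, -2, 7), scale = 1.3)
  round_trip <- apply_transform(apply_transform(pc, rt), invert_transform(rt))
  expect_lt(max(abs(round_trip$points - pc$points)), 1e-9)

  nm_pc <- point_cloud(pc$points, space = "nm")
  expect_error(apply_transform(nm_pc, rt), "space mismatch")

  phys <- to_physical(rigid_transform(translation = c(5, -3, 2)), 20)
  expect_equal(phys$translation, c(100, -60, 40))
  expect_equal(phys$units, "nm")
  back <- to_pixel(phys)
  expect_equal(back$translation, c(5, -3, 2))
  expect_error(to_physical(phys, 20), "pixel")
})

test_that("the CPD objective is non-increasing and rotations stay orthonormal", {
  for (s in 1:6) {
    Y <- random_cloud(60, 100 + s)
    R <- rot_about_z(5 * s)
    set.seed(200 + s)
    X <- sweep(Y %*% t(R), 2L, rnorm(3, 0, 3), "+") +
      matrix(rnorm(180, 0, 0.5), ncol = 3)
    fit <- cpd(Y, X, type = "rigid")
    nll <- fit$nll_trace
    expect_true(all(diff(nll) <= 1e-8 * pmax(1, abs(nll[-length(nll)]))))
    Rf <- fit$transform$rotation
    expect_lt(max(abs(crossprod(Rf) - diag(3))), 1e-8)
    expect_gt(det(Rf), 0)
  }
})

test_that("registration is equivariant under a common rigid motion", {
  Y <- random_cloud(150, 49)
  R <- rot_about_z(15)
  X <- sweep(Y %*% t(R), 2L, c(3, 1, -2), "+")
  fit0 <- cpd(Y, X, type = "rigid")

  g_R <- rot_about_z(-40)
  g_t <- c(10, -5, 8)
  Yg <- sweep(Y %*% t(g_R), 2L, g_t, "+")
  Xg <- sweep(X %*% t(g_R), 2L, g_t, "+")
  fitg <- cpd(Yg, Xg, type = "rigid")
  # conjugacy: R_g = g R g^-1
  expect_lt(max(abs(fitg$transform$rotation - g_R %*% fit0$transform$rotation %*% t(g_R))),
            1e-4)
})

test_that("cpd rejects degenerate inputs", {
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(cpd(line, random_cloud(10, 50)), "collinear")
  expect_error(cpd(random_cloud(10, 51), random_cloud(10, 52), w = 1), "w must")
  bad <- random_cloud(10, 53); bad[1, 1] <- NA
  expect_error(cpd(bad, random_cloud(10, 54)), "finite")
})

test_that("cpd_fit methods expose the fit", {
  Y <- random_cloud(50, 55)
  X <- sweep(Y %*% t(rot_about_z(10)), 2L, c(1, 1, 1), "+")
  fit <- cpd(Y, X, type = "rigid")
  expect_output(print(fit), "Coherent point drift")
  expect_output(print(summary(fit)), "objective decreased")
  co <- coef(fit)
  expect_named(co, c("scale", "rotation", "translation"))
  expect_equal(predict(fit, Y), apply_transform(Y, fit$transform))
  expect_s3_class(logLik(fit), "logLik")
})
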