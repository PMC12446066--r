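test_that("overlap_volume counts intersecting voxels in um^3", {
  a <- array(0L, c(10, 10, 10)); a[1:10, 1:10, 1:5] <- 1L
  b <- array(0L, c(10, 10, 10)); b[1:10, 1:10, 1:10] <- 1L
  la <- label_volume(a, 50); lb <- label_volume(b, 50)

  expect_equal(overlap_volume(lb, lb), mask_volume_um3(lb))
  disj <- array(0L, c(10, 10, 10)); disj[1:10, 1:10, 6:10] <- 1L
  expect_equal(overlap_volume(la, label_volume(disj, 50)), 0)

  # half-overlapping constructed masks: 500 shared voxels at (50 nm)^3
  expect_equal(overlap_volume(la, lb), 500 * 1.25e-4)
  expect_error(overlap_volume(la, label_volume(b, 20)), "share")
})

test_that("mesh centroids locate digital spheres and are translation-equivariant", {
  sph <- sphere_labels(6, c(20L, 20L, 20L), voxel_nm = 20)
  cen <- mesh_centroid(sph)
  expect_lt(max(abs(cen - 9.5 * 20)), 20)

  shifted <- label_volume(array(0L, c(24, 24, 24)), 20)
  shifted$labels[(1:20) + 3, (1:20) + 2, (1:20) + 4] <- sph$labels
  cen2 <- mesh_centroid(shifted)
  expect_equal(cen2 - cen, c(3, 2, 4) * 20, tolerance = 1e-9)

  lone <- array(0L, c(5, 5, 5)); lone[3, 3, 3] <- 1L
  cl <- mesh_centroid(label_volume(lone, 20))
  expect_lt(max(abs(cl - 2 * 20)), 10)
  expect_error(mesh_centroid(label_volume(array(0L, c(3, 3, 3)), 20)), "empty")
})

test_that("centroid_distance is a symmetric metric on fixtures", {
  s1 <- sphere_labels(4, c(30L, 30L, 30L), voxel_nm = 20, center = c(8, 8, 8))
  s2 <- sphere_labels(4, c(30L, 30L, 30L), voxel_nm = 20, center = c(13, 8, 8))
  s3 <- sphere_labels(4, c(30L, 30L, 30L), voxel_nm = 20, center = c(8, 20, 8))
  expect_equal(centroid_distance(s1, s1), 0)
  expect_equal(centroid_distance(s1, s2), 100, tolerance = 20)
  expect_equal(centroid_distance(s1, s2), centroid_distance(s2, s1))
  d12 <- centroid_distance(s1, s2); d23 <- centroid_distance(s2, s3)
  expect_lte(centroid_distance(s1, s3), d12 + d23 + 1e-9)
})

test_that("characteristic_length is the cube root of volume", {
  expect_equal(characteristic_length(1), 1)
  expect_equal(characteristic_length(8), 2)
  expect_equal(characteristic_length(0.029), 0.029^(1/3))
  expect_error(characteristic_length(-1), "non-negative")
})

test_that("landmark errors follow closed-form expectations", {
  set.seed(71)
  mov <- point_cloud(random_cloud(50, 72), space = "pixel", step_nm = 20)
  tr <- rigid_transform(rotation = rot_about_z(17), translation = c(2, -1, 4))
  fixed <- apply_transform(mov, tr)
  expect_lt(max(landmark_errors(mov, fixed, tr)), 1e-9)

  off <- point_cloud(sweep(mov$points, 2L, c(10, 0, 0), "+"), space = "pixel", step_nm = 20)
  errs <- landmark_errors(mov, off, rigid_transform())
  expect_equal(unname(errs), rep(200, 50))  # 10 px at 20 nm

  # mean distance under isotropic 3D Gaussian offsets: sigma * 2 * sqrt(2/pi)
  sigma <- 3
  set.seed(73)
  n <- 4000
  pert <- point_cloud(matrix(rnorm(3 * n, 0, sigma), ncol = 3), space = "pixel", step_nm = 1)
  zero <- point_cloud(matrix(0, n, 3), space = "pixel", step_nm = 1)
  m <- mean(landmark_errors(pert, zero, rigid_transform()))
  expect_lt(abs(m - sigma * 2 * sqrt(2 / pi)) / (sigma * 2 * sqrt(2 / pi)), 0.2)
  expect_error(landmark_errors(mov, point_cloud(mov$points[1:3, ]), tr), "paired")
})

test_that("the landmark noise experiment behaves under null and alternative", {
  set.seed(74)
  mov <- point_cloud(random_cloud(80, 75, 0, 100), space = "pixel", step_nm = 20)
  tr <- rigid_transform(rotation = rot_about_z(8), translation = c(1, 2, 3))
  fixed <- apply_transform(mov, tr)

  # identical transforms: never significant
  null_tab <- landmark_noise_experiment(mov, fixed, tr, tr, n_pixels = c(0, 2, 5),
                                        seeds = 1:3)
  expect_true(all(null_tab$p_value > 0.05, na.rm = TRUE))

  # +1 px systematic error: significant at small noise, washed out by large
  tr_bad <- tr
  tr_bad$translation <- tr$translation + c(1, 1, 1)
  tab <- landmark_noise_experiment(mov, fixed, tr_bad, tr, n_pixels = c(1, 20),
                                   seeds = 1:4)
  p1 <- mean(tab$p_value[tab$n_pixels == 1])
  p20 <- mean(tab$p_value[tab$n_pixels == 20])
  expect_lt(p1, 0.05)
  expect_gt(p20, 0.05)
  expect_error(landmark_noise_experiment(mov, fixed, tr, tr, n_pixels = -1), ">= 0")
})

test_that("ablate_instances removes the requested count with the requested geometry", {
  fx <- small_fixture()
  lab <- fx$em_labels
  expect_identical(ablate_instances(lab, 0)$labels, lab$labels)

  out <- ablate_instances(lab, 0.4, "random", seed = 7)
  ids <- setdiff(unique(as.vector(out$labels)), 0L)
  expect_equal(length(ids), 10 - round(0.4 * 10))

  # ring-plus-center phantom: the central instance survives peripheral removal
  d <- c(5L, 40L, 40L)
  arr <- array(0L, d)
  arr[3, 19:21, 19:21] <- 1L
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  for (i in 1:6) {
    cy <- round(20 + 15 * cos(ang[i])); cx <- round(20 + 15 * sin(ang[i]))
    arr[3, cy + (-1:1), cx + (-1:1)] <- i + 1L
  }
  ring <- label_volume(arr, 20)
  per <- ablate_instances(ring, 5 / 7, "peripheral")
  expect_true(1L %in% unique(as.vector(per$labels)))
  cen <- ablate_instances(ring, 1 / 7, "central")
  expect_false(1L %in% unique(as.vector(cen$labels)))
  expect_error(ablate_instances(ring, 1), "fraction")
})

test_that("proximity correlation matches a brute-force rank oracle", {
  lm <- sphere_labels(3, c(40L, 40L, 40L), voxel_nm = 20, center = c(5, 5, 5))
  targets <- lapply(c(10, 18, 26, 34), function(x)
    sphere_labels(2, c(40L, 40L, 40L), voxel_nm = 20, center = c(5, 5, x)))

  dists <- c(10, 20, 30, 40)  # monotone with proximity order
  expect_equal(proximity_correlation(targets, lm, dists), 1)
  expect_equal(proximity_correlation(targets, lm, rev(dists)), -1)

  # ties: compare against an average-rank brute-force computation
  tied <- c(5, 5, 9, 1)
  rho <- proximity_correlation(targets, lm, tied)
  prox <- vapply(targets, function(tg) {
    cen <- mesh_centroid(tg)
    lm_nm <- sweep(which(lm$labels > 0L, arr.ind = TRUE) - 1, 2L, c(20, 20, 20), "*")
    sqrt(min(rowSums(sweep(lm_nm, 2L, cen)^2)))
  }, numeric(1))
  avg_rank <- function(x) {
    sapply(seq_along(x), function(i) mean(which(sort(x) == x[i])))
  }
  r1 <- avg_rank(prox); r2 <- avg_rank(tied)
  oracle <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  expect_equal(rho, oracle, tolerance = 1e-12)
  expect_error(proximity_correlation(targets[1:2], lm, dists[1:2]), "3 targets")
})
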