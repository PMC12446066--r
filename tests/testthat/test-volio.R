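test_that("TIFF stacks round-trip for intensity and label volumes", {
  v <- volume(array(runif(10 * 32 * 32), c(10, 32, 32)), c(50, 7, 7), channel = "mito")
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(v, path)
  v2 <- read_stack(path, c(50, 7, 7))
  expect_equal(dim(v2$data), c(10, 32, 32))
  expect_equal(v2$data, v$data, tolerance = 1e-6)
  expect_equal(v2$voxel_size, c(50, 7, 7))

  lab <- label_volume(array(sample(0:5, 4 * 8 * 8, replace = TRUE), c(4, 8, 8)), 25)
  lp <- withr::local_tempfile(fileext = ".tif")
  write_stack(lab, lp)
  lab2 <- read_label_stack(lp, 25)
  expect_identical(lab2$labels, lab$labels)
})

test_that("read_stack rejects degenerate inputs", {
  expect_error(read_stack(tempfile(), c(1, 1, 1)), "not found")
  single <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4, 4), single)
  expect_error(read_stack(single, c(10, 10, 10)), ">=2 z-slices")
  multi <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4), matrix(0.5, 4, 4)), multi)
  expect_error(read_stack(multi, c(0, 5, 5)), "positive")
})

test_that("resample_isotropic follows the round(extent/target) shape rule", {
  v <- volume(array(runif(10 * 100 * 100), c(10, 100, 100)), c(50, 7, 7))
  out <- resample_isotropic(v, 50)
  expect_equal(dim(out$data), c(10, 14, 14))
  expect_equal(out$voxel_size, c(50, 50, 50))
  # extent preserved within one voxel per axis
  expect_true(all(abs(dim(out$data) * 50 - c(10, 100, 100) * c(50, 7, 7)) <= 50))

  iso <- volume(array(runif(5 * 6 * 7), c(5, 6, 7)), c(20, 20, 20))
  expect_equal(resample_isotropic(iso, 20)$data, iso$data)

  lab <- label_volume(array(sample(c(0L, 3L), 6 * 30 * 30, replace = TRUE), c(6, 30, 30)),
                      c(40, 10, 10))
  out2 <- resample_isotropic(lab, 20)
  expect_true(all(unique(as.vector(out2$labels)) %in% c(0L, 3L)))
  expect_error(resample_isotropic(lab, 20, "linear"), "nearest")
})

test_that("label volumes survive a resampling round trip within the nearest-neighbor bound", {
  fx <- small_fixture()
  orig <- fx$em_labels
  down <- resample_isotropic(orig, 40, "nearest")
  back <- resample_isotropic(down, orig$voxel_size[1], "nearest")
  n0 <- tabulate(orig$labels[orig$labels > 0L])
  n1 <- tabulate(back$labels[back$labels > 0L], nbins = length(n0))
  big <- which(n0 >= 100)
  expect_true(length(big) > 0)
  expect_true(all(abs(n1[big] - n0[big]) / n0[big] < 0.30))
})

test_that("bin_volume computes block means and conserves integrated intensity", {
  const <- volume(array(3.5, c(4, 4, 4)), 10)
  expect_true(all(bin_volume(const, c(2, 2, 2))$data == 3.5))

  set.seed(11)
  v <- volume(array(runif(4 * 4 * 4), c(4, 4, 4)), c(10, 10, 10))
  out <- bin_volume(v, c(2, 2, 2))
  # explicit block-mean oracle
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    blk <- v$data[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), (2 * k - 1):(2 * k)]
    expect_equal(out$data[i, j, k], mean(blk))
  }
  expect_equal(out$voxel_size, c(20, 20, 20))
  # intensity x voxel-volume conserved for exact tiling
  expect_equal(sum(out$data) * prod(out$voxel_size),
               sum(v$data) * prod(v$voxel_size), tolerance = 1e-12)
  expect_equal(bin_volume(v, c(1, 1, 1))$data, v$data)
  expect_error(bin_volume(v, c(5, 1, 1)), "exceeds")
})

test_that("merge_masks_by_sum is a voxelwise union with relabeling", {
  set.seed(5)
  a <- array(0L, c(4, 10, 10)); a[2, 2:4, 2:4] <- 1L
  b <- array(0L, c(4, 10, 10)); b[3, 6:8, 6:8] <- 1L
  c3 <- array(0L, c(4, 10, 10)); c3[2:3, 3:7, 3:7] <- 1L
  la <- label_volume(a, 20); lb <- label_volume(b, 20); lc <- label_volume(c3, 20)

  same <- merge_masks_by_sum(list(la, la))
  expect_equal(same$labels > 0L, a > 0L)

  dis <- merge_masks_by_sum(list(la, lb))
  expect_equal(sum(dis$labels > 0L), sum(a) + sum(b))

  all3 <- merge_masks_by_sum(list(la, lb, lc))
  expect_equal(all3$labels > 0L, (a | b | c3))

  bad <- label_volume(array(0L, c(4, 10, 10)), 25)
  expect_error(merge_masks_by_sum(list(la, bad)), "mismatch")
})

test_that("point clouds and transforms round-trip through CSV and JSON", {
  pc <- point_cloud(matrix(rnorm(30) * 100, ncol = 3), space = "pixel",
                    step_nm = 20, source = "fm")
  path <- withr::local_tempfile(fileext = ".csv")
  write_point_cloud(pc, path)
  pc2 <- read_point_cloud(path)
  expect_lt(max(abs(pc2$points - pc$points)), 1e-9)
  expect_equal(pc2$space, "pixel")
  expect_equal(pc2$step_nm, 20)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# space=pixel", "z,y", "1,2"), bad)
  expect_error(read_point_cloud(bad), "columns")
  nohdr <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("z,y,x", "1,2,3"), nohdr)
  expect_error(read_point_cloud(nohdr), "header")

  th <- 0.4
  tr <- rigid_transform(rotation = rot_about_z(23), translation = c(5, -3, 2),
                        scale = 1.25)
  jp <- withr::local_tempfile(fileext = ".json")
  write_transform(tr, jp)
  tr2 <- read_transform(jp)
  expect_equal(tr2$rotation, tr$rotation)
  expect_equal(tr2$translation, tr$translation)
  expect_equal(tr2$scale, tr$scale)

  af <- affine_transform(matrix = matrix(c(1, .2, 0, 0, 1.1, 0, .1, 0, .9), 3, 3),
                         translation = c(1, 2, 3))
  write_transform(af, jp)
  af2 <- read_transform(jp)
  expect_equal(af2$matrix, af$matrix)

  ctrl <- random_cloud(8, 2, 0, 10)
  f <- tps_fit(ctrl, ctrl + 0.5)
  write_transform(f, jp)
  f2 <- read_transform(jp)
  expect_equal(f2$weights, f$weights, tolerance = 1e-12)
  expect_equal(f2$control, f$control)
})
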