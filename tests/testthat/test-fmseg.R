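test_that("minmax_normalize maps extremes to 0 and 1 and rejects constants", {
  v <- volume(array(c(2, 4, 6, 2, 4, 6, 2, 4), c(2, 2, 2)), 10)
  out <- minmax_normalize(v)
  expect_equal(sort(unique(as.vector(out$data))), c(0, 0.5, 1))
  ok <- volume(array(seq(0, 1, length.out = 8), c(2, 2, 2)), 10)
  out2 <- minmax_normalize(ok)
  expect_equal(range(out2$data), c(0, 1))
  expect_error(minmax_normalize(volume(array(5, c(2, 2, 2)), 10)), "constant")
})

test_that("dog_filter obeys the 1.6 scale-ratio rule and annihilates constants", {
  s <- dog_sigmas(3.0)
  expect_identical(unname(s[2]), 3.0 * 1.6)
  expect_error(dog_sigmas(-1), "sigma")
  expect_error(dog_sigmas(3, ratio = 0.9), "ratio")

  const <- volume(array(0.7, c(8, 8, 8)), 10)
  expect_lt(max(abs(dog_filter(const, 2)$data)), 1e-12)
})

test_that("dog_filter impulse response equals the separable DoG kernel", {
  n <- 33L
  imp <- array(0, c(n, n, n)); imp[17, 17, 17] <- 1
  resp <- dog_filter(volume(imp, 10), sigma = 2.0)$data
  # independent oracle: outer product of 1D Gaussian kernels
  g1d <- function(sig) { r <- ceiling(4 * sig); x <- -r:r
                         k <- exp(-x^2 / (2 * sig^2)); k / sum(k) }
  dense <- function(sig) {
    k <- g1d(sig); r <- (length(k) - 1) / 2
    arr <- array(0, c(n, n, n))
    for (a in seq_along(k)) for (b in seq_along(k)) for (cc in seq_along(k)) {
      arr[17 + a - r - 1, 17 + b - r - 1, 17 + cc - r - 1] <- k[a] * k[b] * k[cc]
    }
    arr
  }
  expect_equal(resp, dense(2.0) - dense(3.2), tolerance = 1e-12)
  expect_equal(which(resp == max(resp)), which(imp == 1))
})

test_that("dog_filter is linear in its input", {
  set.seed(8)
  v <- array(runif(6 * 12 * 12), c(6, 12, 12))
  r1 <- dog_filter(volume(v, 10), 1.5)$data
  r2 <- dog_filter(volume(3.7 * v, 10), 1.5)$data
  expect_equal(r2, 3.7 * r1, tolerance = 1e-10)
})

test_that("dynamic_threshold follows the slice rule and is monotone in T", {
  # uniform positive slice, positive-part statistic: m > 1.2 m is false
  u <- volume(array(0.3, c(2, 6, 6)), 10)
  expect_equal(sum(dynamic_threshold(u, 1.2, stat = "positive_mean")$labels), 0L)

  # single positive voxel: kept iff value > T x slice statistic
  sl <- array(0, c(1, 10, 10)); sl[1, 5, 5] <- 1
  v <- volume(sl, 10)
  stat <- mean(pmax(sl[1, , ], 0))
  kept <- dynamic_threshold(v, 1.2, stat = "positive_mean")$labels[1, 5, 5]
  expect_identical(kept, as.integer(1 > 1.2 * stat))

  # T = 0 keeps all strictly positive responses
  set.seed(3)
  r <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  out0 <- dynamic_threshold(volume(r, 10), 0, stat = "positive_mean")
  expect_equal(out0$labels == 1L, r > 0)

  # monotone non-increasing in T (set inclusion)
  prev <- NULL
  for (T in c(0, 0.5, 1, 2, 4)) {
    cur <- dynamic_threshold(volume(r, 10), T, stat = "positive_mean")$labels
    if (!is.null(prev)) expect_true(all(prev[cur == 1L] == 1L))
    prev <- cur
  }

  # reference statistic: noise-only reference slices yield empty masks when
  # the reference carries no signal above the response
  ref <- volume(array(0.001, c(4, 8, 8)), 10)
  outr <- dynamic_threshold(volume(abs(r) * 2e-4, 10), 1.2, reference = ref)
  expect_equal(sum(outr$labels), 0L)
  expect_error(dynamic_threshold(volume(r, 10), 1.2, stat = "reference_mean"),
               "reference")
})

test_that("size_filter keeps components inside the percentile band inclusively", {
  # 100 isolated components of sizes 1..100: contiguous runs on separated rows
  d <- c(2L, 302L, 102L)
  arr <- array(0L, d)
  for (s in 1:100) arr[1, 3 * s, seq_len(s)] <- 1L
  mask <- label_volume(arr, 10)
  out <- size_filter(mask, 5, 95)
  sizes_kept <- sort(unique(tabulate(out$labels[out$labels > 0L])))
  bounds <- quantile(1:100, c(0.05, 0.95), type = 7, names = FALSE)
  expect_equal(sizes_kept, (1:100)[1:100 >= bounds[1] & 1:100 <= bounds[2]])

  # a single component is retained (both percentiles equal its size)
  one <- array(0L, c(2, 5, 5)); one[1, 2:3, 2:3] <- 1L
  kept <- size_filter(label_volume(one, 10))
  expect_equal(sum(kept$labels > 0L), 4L)

  empty <- size_filter(label_volume(array(0L, c(2, 4, 4)), 10))
  expect_equal(sum(empty$labels), 0L)

  # output component-size set is a subset of the input sizes at any band
  outr <- size_filter(mask, 20, 80)
  out_sizes <- tabulate(outr$labels[outr$labels > 0L])
  expect_true(all(out_sizes %in% 1:100))
  expect_lt(length(out_sizes), 100L)
})

test_that("Yen clipping matches an exhaustive-threshold oracle", {
  set.seed(4)
  x <- c(rnorm(500, 10, 1), rnorm(20, 255, 1))
  v <- volume(array(sample(x, 512), c(8, 8, 8)), 10)
  th <- yen_threshold(v$data)
  # exhaustive oracle over all histogram splits
  h <- hist(as.vector(v$data), breaks = seq(min(v$data), max(v$data), length.out = 257),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  best <- -Inf; best_t <- NA
  for (t in 1:255) {
    p1 <- sum(p[1:t]); p1sq <- sum(p[1:t]^2); p2sq <- sum(p[(t + 1):256]^2)
    if (p1sq <= 0 || p2sq <= 0 || p1 <= 0 || p1 >= 1) next
    crit <- -log(p1sq * p2sq) + 2 * log(p1 * (1 - p1))
    if (crit > best) { best <- crit; best_t <- h$mids[t] }
  }
  expect_equal(th, best_t, tolerance = 1e-8)

  clipped <- clip_overexposed(v)
  expect_true(all(clipped$data <= th))
  expect_equal(clipped$data[v$data <= th], v$data[v$data <= th])

  const <- volume(array(1, c(2, 2, 2)), 10)
  expect_equal(clip_overexposed(const)$data, const$data)
})

test_that("Otsu segmentation separates bimodal data and handles degenerate rois", {
  set.seed(6)
  vals <- sample(c(rep(10, 256), rep(200, 256)))
  v <- volume(array(vals, c(8, 8, 8)), 10)
  th <- otsu_threshold(v$data)
  expect_gt(th, 10); expect_lt(th, 200)
  seg <- otsu_segment(v)
  expect_equal(seg$labels == 1L, v$data == 200)

  expect_equal(sum(otsu_segment(volume(array(1, c(4, 4, 4)), 10))$labels), 0L)
  expect_error(otsu_segment(v, rbind(c(0, 0, 0), c(10, 2, 2))), "roi")

  # blurred sphere: segmented count within 20% of the sphere voxel count
  sph <- sphere_labels(6, c(20L, 20L, 20L))
  blurred <- clemalign:::gaussian_blur3(sph$labels * 1.0, rep(1, 3)) +
    array(rnorm(8000, 0, 0.01), c(20, 20, 20))
  seg2 <- otsu_segment(volume(pmax(blurred, 0), 20))
  expect_lt(abs(sum(seg2$labels) - sum(sph$labels)) / sum(sph$labels), 0.2)
})

test_that("segment_fm recovers the fixture instances and tolerates pure noise", {
  fx <- small_fixture()
  m <- segment_fm(fx$fm_landmark, size_high_pct = 100)
  n_true <- max(fx$em_labels$labels)
  expect_gt(max(m$labels), 0)
  # per-instance recovery at IoU-like criterion: map truth into FM space is
  # exercised at pipeline level; here assert the component count is sane
  expect_lt(abs(max(m$labels) - n_true) / n_true, 0.5)

  set.seed(12)
  noise <- volume(array(abs(rnorm(6 * 20 * 20, 0, 1)), c(6, 20, 20)), c(80, 40, 40))
  out <- segment_fm(noise, threshold = 50)
  expect_equal(sum(out$labels), 0L)
})
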