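# Shared fixtures and independent oracles, built in code at test time.

# cache for expensive shared objects (standard fixture + pipeline stages)
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

standard_fixture <- function() {
  cached("fx", generate_fixture(fixture_spec(seed = 1L)))
}

# isotropically resampled masks of the standard fixture at the default grid
standard_masks <- function() {
  cached("masks", {
    fx <- standard_fixture()
    fm_mask <- segment_fm(fx$fm_landmark, size_high_pct = 100)
    list(fm_iso = resample_isotropic(fm_mask, 20, "nearest"),
         em_iso = resample_isotropic(fx$em_labels, 20, "nearest"))
  })
}

standard_surfaces <- function() {
  cached("surf", {
    m <- standard_masks()
    list(fm = surface_points(m$fm_iso), em = surface_points(m$em_iso))
  })
}

# a small fixture for fast pipeline-level tests
small_fixture_spec <- function(seed = 3L) {
  fixture_spec(seed = seed, shape = c(48L, 160L, 160L), n_mito = 10L,
               mito_major_nm = c(500, 700), mito_minor_nm = c(300, 400),
               n_targets = 2L, target_diam_nm = c(300, 600))
}

small_fixture <- function() {
  cached("fx_small", generate_fixture(small_fixture_spec()))
}

# digital sphere / ellipsoid label volume centred in the grid
sphere_labels <- function(radius, shape = rep(2L * ceiling(radius) + 5L, 3L),
                          voxel_nm = 20, center = (shape - 1) / 2) {
  idx <- as.matrix(expand.grid(z = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                               x = 0:(shape[3] - 1)))
  inside <- rowSums(sweep(idx, 2L, center)^2) <= radius^2
  label_volume(array(as.integer(inside), shape), voxel_nm)
}

# random rotation about the z axis plus translation, as matrix/vector
rot_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3, byrow = TRUE)
}

random_cloud <- function(n, seed, lo = 0, hi = 50) {
  set.seed(seed)
  matrix(runif(3 * n, lo, hi), ncol = 3)
}

# independent dense trilinear sampler used as the warp oracle (per-point loop)
oracle_trilinear <- function(arr, p) {
  d <- dim(arr)
  val <- 0
  lo <- floor(p)
  f <- p - lo
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    q <- lo + c(a, b, cc)
    if (any(q < 0) || any(q > d - 1)) next
    w <- prod(ifelse(c(a, b, cc) == 1, f, 1 - f))
    val <- val + w * arr[q[1] + 1, q[2] + 1, q[3] + 1]
  }
  val
}
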