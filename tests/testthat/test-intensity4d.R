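test_that("quantization maps the ROI range linearly and handles degeneracy", {
  v <- array(0:255, c(8, 8, 4))
  m <- binary_mask(array(1L, c(8, 8, 4)))
  lev <- quantize_intensities(voxel_volume(v), m, 256)
  expect_identical(as.vector(lev), 0:255)

  const <- quantize_intensities(voxel_volume(array(3.7, c(4, 4, 4))),
                                binary_mask(array(1L, c(4, 4, 4))), 16)
  expect_true(all(const == 0))

  set.seed(5)
  vv <- array(rnorm(6^3), c(6, 6, 6))
  lev2 <- quantize_intensities(voxel_volume(vv), binary_mask(array(1L, c(6, 6, 6))), 16)
  expected <- pmin(floor((vv - min(vv)) / (max(vv) - min(vv)) * 16), 15)
  expect_identical(as.vector(lev2), as.integer(expected))
})

test_that("the 4D lift occupies exactly one cell per ROI voxel", {
  v <- array(0, c(2, 1, 1)); v[1] <- 0; v[2] <- 3
  m <- binary_mask(array(1L, c(2, 1, 1)))
  occ <- lift_to_4d(voxel_volume(v), m, n_levels = 4)
  expect_equal(dim(occ$occ), c(2, 1, 1, 4))
  expect_equal(sum(occ$occ), 2)
  expect_equal(occ$occ[1, 1, 1, 1], 1L)   # min intensity -> level 0
  expect_equal(occ$occ[2, 1, 1, 4], 1L)   # max intensity -> top level

  set.seed(3)
  vol <- array(rnorm(8^3), c(8, 8, 8))
  msk <- array(as.integer(rbinom(8^3, 1, 0.5)), c(8, 8, 8)); msk[1] <- 1L
  occ2 <- lift_to_4d(voxel_volume(vol), binary_mask(msk))
  expect_equal(sum(occ2$occ), sum(msk))
})

test_that("the subsampling engine at rate 1 equals the exact engine", {
  g <- make_gradient_intensity(16, noise_sd = 0.05, seed = 3)
  occ <- lift_to_4d(g$volume, g$mask)
  ex <- lacunarity_4d(occ, rate = 1)                       # integral-image path
  sm <- lacunarity_4d(occ, rate = 1, method = "sample")    # full enumeration
  expect_equal(sm$curve$value, ex$curve$value, tolerance = 1e-12)
  expect_equal(sm$slope, ex$slope, tolerance = 1e-12)
})

test_that("one constant-ROI window reproduces Lambda = n_levels in closed form", {
  # constant ROI filling its box: occupancy fills one level-slab, so a window
  # spanning the whole 4D box has fill 1/n_levels and CV^2 = (1-p)/p
  n <- 4; L <- 4
  v <- voxel_volume(array(2.5, c(n, n, n)))
  m <- binary_mask(array(1L, c(n, n, n)))
  occ <- lift_to_4d(v, m, n_levels = L)
  lam <- window_lacunarity(occ$occ, s = 4, stride_mode = "grid")
  expect_equal(lam, L, tolerance = 1e-12)
})

test_that("subsampled occupancy means are unbiased over many seeds", {
  # single-window fixture: invert Lambda_hat to mu_hat and average over seeds
  set.seed(8)
  occ <- array(as.integer(rbinom(4^4, 1, 0.4)), c(4, 4, 4, 4))
  mu_true <- mean(occ)
  mus <- vapply(1:250, function(sd) {
    lam <- lacunarity_4d_at_scale(occ, 4, rate = 0.25, seed = sd,
                                  method = "sample")
    1 / (1 + (lam - 1))   # CV^2 = (1 - mu) / mu  =>  mu = 1 / (1 + CV^2)
  }, numeric(1))
  expect_equal(mean(mus), mu_true, tolerance = 0.02)
})

test_that("fixed seed gives bit-identical subsampled LI across worker counts", {
  g <- make_gradient_intensity(16, noise_sd = 0.1, seed = 6)
  occ <- lift_to_4d(g$volume, g$mask)
  a <- lacunarity_4d(occ, rate = 0.05, seed = 9, workers = 1)
  b <- lacunarity_4d(occ, rate = 0.05, seed = 9, workers = 4)
  c2 <- lacunarity_4d(occ, rate = 0.05, seed = 9, workers = 1)
  expect_identical(a$curve$value, c2$curve$value)
  expect_equal(a$curve$value, b$curve$value, tolerance = 1e-12)
  d <- lacunarity_4d(occ, rate = 0.05, seed = 10)
  expect_false(identical(a$curve$value, d$curve$value))
})

test_that("LI is invariant to affine intensity rescaling", {
  g <- make_gradient_intensity(16, noise_sd = 0.2, seed = 12)
  occ1 <- lift_to_4d(g$volume, g$mask)
  v2 <- voxel_volume(3 * g$volume$data + 10, g$volume$spacing)
  occ2 <- lift_to_4d(v2, g$mask)
  expect_identical(occ1$occ, occ2$occ)
  l1 <- lacunarity_4d(occ1, rate = 0.02, seed = 2)
  l2 <- lacunarity_4d(occ2, rate = 0.02, seed = 2)
  expect_identical(l1$slope, l2$slope)
})

test_that("measure_patient composes the three measures deterministically", {
  m <- make_menger(3)
  flair <- voxel_volume(array(1.0, c(27, 27, 27)))
  f1 <- measure_patient(m, flair, scales_fd = c(1, 3, 9, 27), seed = 4)
  f2 <- measure_patient(m, flair, scales_fd = c(1, 3, 9, 27), seed = 4)
  expect_identical(f1, f2)
  expect_equal(f1$fd, log(20) / log(3), tolerance = 1e-6)
  expect_equal(f1$volume_cm3, 8.0)      # 20^3 voxels at 1 mm^3
  expect_true(is.na(f1$cystic))

  bad <- voxel_volume(array(1.0, c(20, 20, 20)))
  expect_error(measure_patient(m, bad), "mismatch")
})
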