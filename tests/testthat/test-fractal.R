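test_that("log-log slope fit recovers exact power laws and degenerate curves", {
  s <- c(2, 4, 8, 16)
  f <- fit_loglog_slope(s, (1 / s)^3)
  expect_equal(f$slope, 3.0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1.0, tolerance = 1e-12)

  flat <- fit_loglog_slope(s, rep(7, 4))
  expect_identical(flat$slope, 0)
  expect_identical(flat$r_squared, 1)

  sponge <- fit_loglog_slope(c(1, 3, 9, 27), c(8000, 400, 20, 1))
  expect_equal(sponge$slope, log(20) / log(3), tolerance = 1e-9)

  expect_error(fit_loglog_slope(c(2, 4), c(1, 2)), "3 points")
  expect_error(fit_loglog_slope(s, c(1, 2, 0, 4)), "> 0")
})

test_that("fractal dimension hits the analytic anchors", {
  m3 <- make_menger(3)
  fd <- fractal_dimension(m3, scales = c(1, 3, 9, 27))
  expect_equal(fd$slope, log(20) / log(3), tolerance = 1e-6)
  expect_equal(fd$curve$value, c(8000, 400, 20, 1))

  expect_equal(fractal_dimension(make_solid("cube", 64))$slope, 3, tolerance = 0.15)
  expect_gt(fractal_dimension(make_solid("slab", 64))$slope, 1.85)
  expect_lt(fractal_dimension(make_solid("slab", 64))$slope, 2.1)
  expect_gt(fractal_dimension(make_solid("line", 64))$slope, 0.9)
  expect_lt(fractal_dimension(make_solid("line", 64))$slope, 1.1)
})

test_that("FD is invariant under axis permutation and translation", {
  a <- random_mask_array(14, 0.2, 77)
  pad <- array(0L, c(20, 20, 20))
  pad[3:16, 3:16, 3:16] <- a
  shift <- array(0L, c(20, 20, 20))
  shift[6:19, 5:18, 2:15] <- a
  scales <- c(2, 4, 7)
  f0 <- fractal_dimension(binary_mask(pad), scales)
  expect_identical(f0$curve$value,
                   fractal_dimension(binary_mask(shift), scales)$curve$value)
  expect_identical(f0$curve$value,
                   fractal_dimension(binary_mask(aperm(pad, c(3, 1, 2))), scales)$curve$value)
})

test_that("lacunarity obeys the homogeneous limit and the binary closed form", {
  hom <- array(1, c(12, 12, 12))
  for (s in c(2, 3, 4)) expect_identical(lacunarity_at_scale(hom, s), 1)
  expect_identical(lacunarity_index(array(1, c(16, 16, 16)))$slope, 0)

  # one window over [1, 0]: mu 0.5, pop sd 0.5, CV^2 = 1, Lambda = 2
  expect_equal(lacunarity_at_scale(array(c(1, 0), c(2, 1, 1)), 2,
                                   stride_mode = "grid"), 2, tolerance = 1e-12)

  # fill-p windows: CV^2 = (1 - p) / p
  for (k in c(1, 3, 5, 7)) {
    w <- array(0, c(2, 2, 2)); w[seq_len(k)] <- 1
    p <- k / 8
    expect_equal(lacunarity_at_scale(w, 2, stride_mode = "grid",
                                     normalize = FALSE),
                 (1 - p) / p, tolerance = 1e-12)
  }
})

test_that("Lambda never drops below 1 and equals 1 only for constant windows", {
  for (seed in 1:5) {
    a <- random_mask_array(10, runif(1, 0.1, 0.9), seed + 50)
    for (s in 2:4)
      expect_gte(lacunarity_at_scale(a, s), 1)
  }
})

test_that("a clustered mask is more lacunar than a dispersed one at equal fill", {
  # the classical gliding-box statistic carries the textbook contrast; the
  # per-window CV^2 statistic reverses it (near-empty windows dominate)
  for (seed in 1:3) {
    po <- make_random_porous(16, fill = 0.1, seed = seed)
    cl <- make_clustered(16, n_clusters = 2, fill = 0.1, seed = seed)
    li_po <- lacunarity_index(po, scales = c(2, 4, 8),
                              statistic = "glidingbox")$slope
    li_cl <- lacunarity_index(cl, scales = c(2, 4, 8),
                              statistic = "glidingbox")$slope
    expect_gt(li_cl, li_po)
  }
})

test_that("full measurement pipeline equals the brute-force pipeline oracle", {
  a <- random_mask_array(12, 0.5, 123)
  scales <- c(2, 3, 4)
  li <- lacunarity_index(a, scales = scales)
  lam_oracle <- vapply(scales, function(s)
    oracle_lacunarity(a, s, "gliding", "literal"), numeric(1))
  expect_equal(li$curve$value, lam_oracle, tolerance = 1e-12)
  fd <- fractal_dimension(a, scales = scales)
  cnt_oracle <- vapply(scales, function(s)
    oracle_box_count(a, s, "grid"), numeric(1))
  expect_equal(fd$curve$value, cnt_oracle)
})
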