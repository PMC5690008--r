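test_that("preprocess normalizes and median-filters", {
  g <- small_geometry(8, 6, 4)
  const <- projection_image(matrix(6, 8, 6), "R", 0)
  out <- preprocess(const, monitor_value = 2)
  expect_equal(out$pixels, matrix(3, 8, 6))
  # single impulse on a flat background is removed
  imp <- matrix(1, 9, 9); imp[5, 5] <- 100
  out <- preprocess(projection_image(imp, "R", 0), 1)
  expect_equal(out$pixels, matrix(1, 9, 9))
  expect_error(preprocess(const, 0), "positive")
  # checkerboard at Nyquist: interior equals the 3x3 majority value
  cb <- outer(1:10, 1:10, function(i, j) (i + j) %% 2)
  out <- preprocess(projection_image(cb, "R", 0), 1)
  oracle <- cb
  for (i in 2:9) for (j in 2:9)
    oracle[i, j] <- sort(as.vector(cb[(i - 1):(i + 1), (j - 1):(j + 1)]))[5]
  expect_equal(out$pixels[2:9, 2:9], oracle[2:9, 2:9])
})

test_that("air normalization computes ln(B/R)", {
  B <- projection_image(matrix(1000, 4, 3), "B", 0)
  R <- projection_image(matrix(250, 4, 3), "R", 0)
  r <- air_normalize(R, B)
  expect_equal(r$pixels, matrix(log(4), 4, 3))
  expect_equal(air_normalize(B, B)$pixels, matrix(0, 4, 3))
  Re <- projection_image(matrix(1000 / exp(1), 4, 3), "R", 0)
  expect_equal(air_normalize(Re, B)$pixels, matrix(1, 4, 3))
  # Monte Carlo zeros are floored, not infinite
  Rz <- projection_image(matrix(c(0, rep(250, 11)), 4, 3), "R", 0)
  expect_message(r <- air_normalize(Rz, B), "floored")
  expect_true(all(is.finite(r$pixels)))
  Bbad <- projection_image(matrix(0, 4, 3), "B", 0)
  expect_error(air_normalize(R, Bbad), "non-positive")
})

test_that("partial-arc weights: conjugate rays sum to one", {
  g <- cone_beam_geometry(100, 149.88, c(39.7, 29.8), c(64, 48),
                          arc_start = 0, arc_extent = 200,
                          n_projections = 372)
  W <- partial_arc_weights(g)
  expect_true(all(W >= 0 & W <= 1))
  # 1000 random rays: w(lambda, gamma) + w(conjugate) = 1 when both in arc
  set.seed(8)
  hf <- half_fan_angle(g)
  lam <- runif(1000, 0, 200)
  gam <- runif(1000, -hf, hf)
  lamc <- (lam + 180 + 2 * gam) %% 360
  w1 <- arc_ray_weight(g, lam, gam)
  w2 <- arc_ray_weight(g, lamc, -gam)
  both <- lamc < 200
  expect_true(all(abs((w1 + w2)[both] - 1) < 1e-6))
  expect_true(all(w1[!both] == 1))
  # full-circle arc: complementary rays split the weight equally
  g360 <- small_geometry(64, 48, 360)
  w <- arc_ray_weight(g360, 90, 3)
  wc <- arc_ray_weight(g360, (90 + 180 + 6) %% 360, -3)
  expect_equal(w + wc, 1, tolerance = 1e-12)
  expect_equal(arc_ray_weight(g360, 123.4, 0), 0.5, tolerance = 1e-12)
  # arc shorter than 180 + fan is rejected
  gshort <- cone_beam_geometry(100, 149.88, c(39.7, 29.8), c(64, 48),
                               0, 185, 100)
  expect_error(partial_arc_weights(gshort), "arc too short")
})

test_that("FDK is linear", {
  g <- small_geometry(32, 24, 24)
  projs <- analytic_cylinder_logproj(g, 0.2, 8)
  zero <- lapply(projs, function(p) log_projection(p$pixels * 0, p$angle,
                                                   "raw"))
  rg <- list(dims = c(32, 32, 4), voxel_size = 0.8)
  v0 <- fdk_reconstruct(zero, g, rg)
  expect_true(all(v0$mu == 0))
  v1 <- fdk_reconstruct(projs, g, rg)
  sc <- lapply(projs, function(p) log_projection(p$pixels * 3.7, p$angle,
                                                 "raw"))
  v3 <- fdk_reconstruct(sc, g, rg)
  expect_lt(max(abs(v3$mu - 3.7 * v1$mu)) / max(abs(3.7 * v1$mu)), 1e-9)
  # missing angles are reported
  expect_error(fdk_reconstruct(projs[-3], g, rg), "missing")
})

test_that("FDK recovers a uniform cylinder's attenuation (small case)", {
  mu <- 0.2059
  g <- small_geometry(64, 48, 90)
  projs <- analytic_cylinder_logproj(g, mu, 8)
  vol <- fdk_reconstruct(projs, g, list(dims = c(64, 64, 4),
                                        voxel_size = 0.4))
  ctr <- (seq_len(64) - 0.5) * 0.4 - 12.8
  r2 <- outer(ctr^2, ctr^2, "+")
  sl <- vol$mu[, , 2]
  expect_equal(mean(sl[r2 < 16]), mu, tolerance = 0.03)
  # no cupping on scatter-free data
  ratio <- mean(sl[r2 < 4]) / mean(sl[r2 > 25 & r2 < 36])
  expect_gt(ratio, 0.97); expect_lt(ratio, 1.03)
})

test_that("rotation consistency: shifting the arc start rotates the volume", {
  mu <- 0.21
  g1 <- small_geometry(48, 32, 180)
  # shift by a whole number of angular steps so both scans sample the same
  # set of source positions (modulo relabeling)
  g2 <- cone_beam_geometry(100, 149.88, c(39.7, 29.8), c(48, 32),
                           arc_start = 40, arc_extent = 360,
                           n_projections = 180)
  rg <- list(dims = c(48, 48, 2), voxel_size = 0.5)
  # the cylinder is rotationally symmetric, so both reconstructions agree
  # up to the discrete quadrature of the redundancy window
  v1 <- fdk_reconstruct(analytic_cylinder_logproj(g1, mu, 7), g1, rg)
  v2 <- fdk_reconstruct(analytic_cylinder_logproj(g2, mu, 7), g2, rg)
  expect_lt(max(abs(v1$mu - v2$mu)), 0.01 * mu)
})

test_that("resampling preserves constants, means and identity", {
  m <- matrix(rnorm(64 * 48), 64, 48)
  expect_identical(resample(m, c(64, 48), "bicubic"), m)
  cm <- matrix(4.2, 16, 12)
  up <- resample(cm, c(64, 48), "bicubic")
  expect_equal(up, matrix(4.2, 64, 48), tolerance = 1e-12)
  # gradient: block average preserves the mean exactly
  gr <- outer(seq_len(512), seq_len(256), function(i, j) i + 2 * j)
  dn <- resample(gr, c(256, 128), "block_average")
  expect_equal(mean(dn), mean(gr), tolerance = 1e-12)
  # and stays a gradient (constant second difference along rows)
  expect_equal(max(abs(diff(diff(dn[, 5])))), 0, tolerance = 1e-9)
  expect_error(resample(gr, c(300, 128), "block_average"), "integer")
  # smooth image: bicubic upsampling preserves the mean within 0.1%
  sm <- outer(sin(seq(0, pi, length.out = 32)),
              cos(seq(0, 1, length.out = 24))) + 2
  up2 <- resample(sm, c(128, 96), "bicubic")
  expect_equal(mean(up2), mean(sm), tolerance = 1e-3)
})
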