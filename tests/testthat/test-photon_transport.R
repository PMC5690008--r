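test_that("vacuum phantom: primary equals blank, scatter is zero", {
  ramp <- default_catphan_ramp()
  ph <- volume_from_mu(array(0, dim = c(16, 16, 16)), ramp, 0.5)
  g <- small_geometry(16, 12, 4)
  sp <- spectrum_mono(60)
  sid <- siddon_primary(ph, g, sp, 0)
  expect_equal(sid$primary$pixels, sid$blank$pixels, tolerance = 1e-12)
  mc <- simulate_projection(ph, g, sp, 0, n_histories = 2000, seed = 3)
  expect_true(all(mc$scatter$pixels == 0))
})

test_that("central-ray transmission follows Beer-Lambert", {
  ph <- make_water_air_phantom(cavity_diameter = 0, voxel_size = 0.4, n = 64)
  g <- small_geometry(65, 49, 4)  # odd grid: a pixel centered on the axis
  sid <- siddon_primary(ph, g, spectrum_mono(60), 0)
  trans <- sid$primary$pixels[33, 25] / sid$blank$pixels[33, 25]
  expect_equal(trans, exp(-material_mu("Water", 60) * 20), tolerance = 0.005)
})

test_that("Siddon radiological path matches dense ray marching", {
  ph <- tiny_slab_phantom(thickness = 4, voxel = 0.25, n = 48)
  g <- small_geometry(33, 25, 8)
  sp <- spectrum_mono(60)
  muw <- material_mu("Water", 60)
  for (ang in c(0, 45)) {
    sid <- siddon_primary(ph, g, sp, ang)
    # oblique off-center pixel and the central pixel
    for (px in list(c(17, 13), c(25, 9))) {
      r <- pixel_ray(g, ang, px[1] - 1, px[2] - 1)
      fr <- cbctscatter:::.det_frame(g, ang)
      pt <- fr$corner + (px[1] - 0.5) * fr$du * fr$uhat +
        (px[2] - 0.5) * fr$dv * fr$vhat
      rp <- march_rho_path(ph, fr$src, pt, step = 1e-3)
      tau_oracle <- muw * sum(rp)
      got <- -log(sid$primary$pixels[px[1], px[2]] /
                    sid$blank$pixels[px[1], px[2]])
      expect_equal(got, tau_oracle, tolerance = 0.002)
    }
  }
  # 45-degree central ray crosses the slab at thickness / cos(45)
  sid45 <- siddon_primary(ph, g, sp, 45)
  tau45 <- -log(sid45$primary$pixels[17, 13] / sid45$blank$pixels[17, 13])
  expect_equal(tau45, muw * 4 / cos(pi / 4), tolerance = 0.01)
})

test_that("Woodcock free paths are exponential; acceptance rule is exact", {
  d <- woodcock_free_path(1e5, mu_max = 0.25, seed = 11)
  ks <- suppressWarnings(stats::ks.test(d, "pexp", 0.25))
  expect_gt(ks$p.value, 0.01)
  expect_error(woodcock_free_path(10, 0), "positive")
  # homogeneous phantom: every interaction real; vacuum: all fictitious
  expect_true(all(accept_real(rep(0.25, 100), 0.25)))
  expect_false(any(accept_real(rep(0, 100), 0.25)))
  expect_error(accept_real(0.3, 0.25), "local_mu")
})

test_that("split_and_roulette weight algebra", {
  ph <- photon_state(c(0, 0, 0), c(0, 0, 1), 60, weight = 1)
  # identity configuration
  out <- split_and_roulette(ph, vrt_params(1, 1), aimed = FALSE)
  expect_length(out, 1)
  expect_equal(out[[1]]$weight, 1)
  # survivors of RR carry Ns/Np times the parent weight
  set.seed(1)
  out <- split_and_roulette(photon_state(c(0, 0, 0), c(0, 0, 1), 60, 2),
                            vrt_params(10, 5), aimed = FALSE)
  for (d in out) expect_equal(d$weight, 2 * 5 / 10)
  # aimed daughters carry exactly w / Np
  out <- split_and_roulette(ph, vrt_params(10, 5), aimed = TRUE)
  expect_length(out, 10)
  for (d in out) expect_equal(d$weight, 1 / 10)
})

test_that("split_and_roulette conserves weight in expectation", {
  set.seed(42)
  for (cfgv in list(c(4, 2), c(16, 8))) {
    vrt <- vrt_params(cfgv[1], cfgv[2])
    ph <- photon_state(c(0, 0, 0), c(0, 0, 1), 60, weight = 1)
    nrep <- 20000
    tot <- vapply(seq_len(nrep), function(i) {
      sum(vapply(split_and_roulette(ph, vrt), `[[`, numeric(1), "weight"))
    }, numeric(1))
    se <- stats::sd(tot) / sqrt(nrep)
    expect_lt(abs(mean(tot) - 1), 3 * se)
  }
})

test_that("MC primary is unbiased against the ray tracer (small case)", {
  ph <- tiny_slab_phantom(thickness = 6, voxel = 0.5, n = 32)
  g <- small_geometry(32, 24, 4)
  sp <- spectrum_mono(60)
  sid <- siddon_primary(ph, g, sp, 0, n_sub = 3)
  mc <- simulate_projection(ph, g, sp, 0, n_histories = 5e4,
                            vrt = vrt_params(8, 4), seed = 9, n_batch = 40)
  P <- mc$primary$pixels
  rel <- mc$primary$rel_uncertainty
  z <- abs(P - sid$primary$pixels) / pmax(rel * P, 1e-300)
  expect_gt(mean(z[rel > 0] <= 3), 0.97)
  # every forced-detection score carried weight 1/Np
  wr <- attr(mc$scatter, "wrel_range")
  expect_equal(wr[1], 1 / 8, tolerance = 1e-12)
  expect_equal(wr[2], 1 / 8, tolerance = 1e-12)
})

test_that("doubling the split number leaves the scatter mean unchanged", {
  ph <- tiny_slab_phantom(thickness = 6, voxel = 0.5, n = 32)
  g <- small_geometry(32, 24, 4)
  sp <- spectrum_mono(60)
  a <- simulate_projection(ph, g, sp, 0, 3e4, vrt_params(8, 4), seed = 21)
  b <- simulate_projection(ph, g, sp, 0, 3e4, vrt_params(16, 4), seed = 22)
  ta <- attr(a$scatter, "total_mean"); sa <- attr(a$scatter, "total_se")
  tb <- attr(b$scatter, "total_mean"); sb <- attr(b$scatter, "total_se")
  expect_lt(abs(ta - tb), 3.5 * sqrt(sa^2 + sb^2))
  expect_error(simulate_projection(ph, g, sp, 0, 0), "n_histories")
})

test_that("adaptive smoothing honours its contracts", {
  # constant, noiseless: fixed point
  flat <- projection_image(matrix(7, 32, 24), "S", 0, matrix(0, 32, 24))
  expect_identical(adaptive_smooth(flat)$pixels, flat$pixels)
  expect_error(adaptive_smooth(projection_image(matrix(7, 4, 4), "S", 0)),
               "rel_uncertainty")
  # flat field with 5% noise: at least 5-fold noise reduction
  set.seed(5)
  noisy <- 100 * (1 + 0.05 * matrix(rnorm(64 * 48), 64, 48))
  pin <- projection_image(pmax(noisy, 0), "S", 0, matrix(0.05, 64, 48))
  sm <- adaptive_smooth(pin)
  expect_lt(stats::median(sm$rel_uncertainty), 0.01)
  expect_lt(sqrt(mean((sm$pixels - 100)^2)) / 100, 0.01)
  # linear ramp + noise: < 1% RMS deviation from the true ramp
  truth <- outer(seq(50, 150, length.out = 64), seq(1, 2, length.out = 48))
  noisy2 <- truth + 5 * matrix(rnorm(64 * 48), 64, 48)
  pin2 <- projection_image(pmax(noisy2, 0), "S", 0,
                           5 / pmax(abs(noisy2), 1))
  sm2 <- adaptive_smooth(pin2)
  expect_lt(sqrt(mean((sm2$pixels - truth)^2)) / mean(truth), 0.01)
})

test_that("spectra are normalized and within the table range", {
  sp <- spectrum_kvp(100)
  expect_equal(sum(sp$lines$weight), 1)
  expect_true(all(sp$lines$energy >= 10 & sp$lines$energy <= 150))
  expect_true(all(sp$lines$weight > 0))
  e <- spectrum_mean_energy(sp)
  expect_gt(e, 40); expect_lt(e, 70)
  expect_error(spectrum_mono(5))
})
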