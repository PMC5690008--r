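test_that("corrected_log_projection implements the relaxed correction", {
  mk <- function(m, comp = "r") log_projection(m, 0, "raw")
  m0 <- matrix(2.0, 3, 2)
  r <- mk(m0)
  r_sim <- log_projection(matrix(1.8, 3, 2), 0, "simulated")
  # zero scatter, alpha 0: correction vanishes
  p <- corrected_log_projection(r, r_sim,
                                projection_image(matrix(1, 3, 2), "P", 0),
                                projection_image(matrix(0, 3, 2), "S", 0),
                                correction_params(alpha = 0, beta = 0.7))
  expect_equal(p$pixels, m0)
  expect_equal(p$kind, "corrected")
  # alpha 0, beta 1, P = S: p = r + ln 2
  p <- corrected_log_projection(r, r_sim,
                                projection_image(matrix(3, 3, 2), "P", 0),
                                projection_image(matrix(3, 3, 2), "S", 0),
                                correction_params(alpha = 0, beta = 1))
  expect_equal(p$pixels, m0 + log(2))
  # hand evaluation: r=2, r_sim=1.8, alpha=.5, beta=.5, P=1, S=0.4
  p <- corrected_log_projection(r, r_sim,
                                projection_image(matrix(1, 3, 2), "P", 0),
                                projection_image(matrix(0.4, 3, 2), "S", 0),
                                correction_params(alpha = 0.5, beta = 0.5))
  expect_equal(p$pixels[1, 1], 3.0 - 0.9 + log(1.2), tolerance = 1e-12)
  expect_equal(p$pixels[1, 1], 2.28232, tolerance = 1e-5)
  # shape mismatch
  expect_error(corrected_log_projection(r, r_sim,
                 projection_image(matrix(1, 2, 2), "P", 0),
                 projection_image(matrix(0, 2, 2), "S", 0),
                 correction_params()), "shape")
})

test_that("beta equals the ratio of scatter-to-primary ratios", {
  expect_equal(grid_beta(1.2, 1.2), 1)
  expect_equal(grid_beta(0.45, 0.9), 0.5)
  expect_error(grid_beta(1, 0), "positive")
  # primary-fraction identity: P/(P + beta S) = 1/(1 + beta SPR)
  set.seed(2)
  for (i in 1:50) {
    P <- runif(1, 0.1, 10); S <- runif(1, 0, 5); b <- runif(1, 0.05, 1)
    expect_equal(P / (P + b * S), 1 / (1 + b * (S / P)), tolerance = 1e-12)
  }
})

test_that("beta = 1 reproduces the grid-free correction exactly", {
  r <- log_projection(matrix(1.5, 4, 4), 0, "raw")
  r_sim <- log_projection(matrix(1.4, 4, 4), 0, "simulated")
  P <- projection_image(matrix(2, 4, 4), "P", 0)
  S <- matrix(0.8, 4, 4)
  p1 <- corrected_log_projection(r, r_sim, P, projection_image(S, "S", 0),
                                 correction_params(alpha = 0, beta = 1))
  # beta folded into the scatter image instead
  b <- 0.6
  p2 <- corrected_log_projection(r, r_sim, P,
                                 projection_image(b * S, "S", 0),
                                 correction_params(alpha = 0, beta = 1))
  p3 <- corrected_log_projection(r, r_sim, P, projection_image(S, "S", 0),
                                 correction_params(alpha = 0, beta = b))
  expect_equal(p2$pixels, p3$pixels, tolerance = 1e-14)
  expect_equal(p1$pixels, r$pixels - log(2 / 2.8), tolerance = 1e-12)
})

test_that("parameter validation", {
  expect_error(correction_params(beta = 0), "beta")
  expect_error(correction_params(max_iter = -1), "max_iter")
  expect_error(correction_params(conv_tol = 0), "conv_tol")
})

# a miniature end-to-end configuration that runs in seconds
tiny_config <- function(seed = 5, max_iter = 3, alpha = 0) {
  geom <- cone_beam_geometry(100, 149.88, c(39.7, 29.8), c(24, 18),
                             0, 360, 12)
  params <- correction_params(alpha = alpha, beta = 1, max_iter = max_iter,
                              conv_tol = 1e-6)
  correction_config(geom, spectrum_mono(60), params, make_mono_ramp(60),
                    vrt = vrt_params(8, 4), n_histories = 3000,
                    recon_grid = list(dims = c(32, 32, 24),
                                      voxel_size = 0.7),
                    scoring_pixels = c(24L, 18L), seed = seed,
                    replicate_projections = TRUE, rmse_radius_cm = 11)
}

tiny_raw <- function(cfg) {
  ph <- make_water_air_phantom(voxel_size = 0.7,
                               n = 32)
  fx <- list(phantom = ph, config = cfg, seed = cfg$seed)
  simulate_raw_scan(fx)
}

test_that("run_correction honours max_iter and records a trace", {
  cfg <- tiny_config(max_iter = 3)
  raw <- suppressMessages(tiny_raw(cfg))
  res <- suppressMessages(suppressWarnings(
    run_correction(raw, cfg$params, cfg)))
  expect_equal(vapply(res$states, function(s) s$iteration, integer(1)),
               0:(length(res$states) - 1))
  expect_lte(length(res$states), 4)
  expect_equal(nrow(res$trace), length(res$states))
  expect_true(all(res$trace$rmse_vs_prev[-1] >= 0))
  # max_iter = 0 returns the uncorrected reconstruction untouched
  cfg0 <- tiny_config(max_iter = 0)
  res0 <- suppressMessages(run_correction(raw, cfg0$params, cfg0))
  expect_length(res0$states, 1)
  expect_equal(res0$states[[1]]$iteration, 0L)
  expect_identical(res0$states[[1]]$volume$mu,
                   fdk_reconstruct(raw$r, cfg0$geometry, cfg0$recon_grid,
                                   hu_scale = cfg0$mu_water)$mu)
})

test_that("zero simulated scatter with alpha = 0 is a fixed point", {
  # algebraic route: the corrected projections equal the raw ones, so the
  # reconstruction is unchanged up to floating-point round-off
  cfg <- tiny_config()
  raw <- suppressMessages(tiny_raw(cfg))
  g <- cfg$geometry
  ang <- arc_angles(g)
  zeroS <- projection_image(matrix(0, 24, 18), "S", 0)
  oneP <- projection_image(matrix(1, 24, 18), "P", 0)
  corr <- lapply(seq_along(ang), function(a) {
    rs <- log_projection(raw$r[[a]]$pixels, ang[a], "simulated")
    p <- corrected_log_projection(raw$r[[a]], rs, oneP, zeroS,
                                  correction_params(alpha = 0, beta = 1))
    log_projection(p$pixels, ang[a], "corrected")
  })
  v1 <- fdk_reconstruct(raw$r, g, cfg$recon_grid)
  v2 <- fdk_reconstruct(corr, g, cfg$recon_grid)
  expect_equal(v2$mu, v1$mu, tolerance = 1e-12)
})

test_that("iteration counter and convergence metric behave", {
  cfg <- tiny_config(max_iter = 1)
  raw <- suppressMessages(tiny_raw(cfg))
  v0 <- fdk_reconstruct(raw$r, cfg$geometry, cfg$recon_grid,
                        hu_scale = cfg$mu_water)
  st0 <- iteration_state(0L, v0)
  st1 <- suppressMessages(run_iteration(st0, raw, cfg))
  expect_equal(st1$iteration, 1L)
  expect_gte(st1$convergence_metric, 0)
  expect_length(st1$corrected_projections, cfg$geometry$n_projections)
})
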