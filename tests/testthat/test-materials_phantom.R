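test_that("ramp assignment follows the half-open interval convention", {
  ramp <- default_catphan_ramp()
  expect_equal(assign_material(0.243, ramp), "Water")
  expect_equal(assign_material(1e-5, ramp), "Vacuum")
  # lower bound inclusive
  expect_equal(assign_material(0.23, ramp), "Water")
  expect_equal(assign_material(0.251, ramp), "Acrylic")
  expect_equal(assign_material(10, ramp), "Teflon")
  expect_error(assign_material(-0.1, ramp), "non-negative")
})

test_that("ramp round-trip: every material's nominal mu maps to itself", {
  ramp <- default_catphan_ramp()
  e <- ramp$entries[ramp$entries$material_name != "Vacuum", ]
  for (i in seq_len(nrow(e))) {
    expect_equal(assign_material(e$mu_mat[i], ramp), e$material_name[i])
    expect_equal(mu_to_density(e$mu_mat[i], e$material_name[i]),
                 e$rho_mat[i])
  }
})

test_that("fractional density conversion", {
  expect_equal(mu_to_density(0.200, "LDPE"), 0.93)
  expect_equal(mu_to_density(0, "Vacuum"), 0)
  # hand evaluation: 0.1 / 0.178 * 0.83
  expect_equal(mu_to_density(0.1, "PMP"), 0.46629213, tolerance = 1e-7)
  expect_error(mu_to_density(-1, "Water"), "non-negative")
})

test_that("ramp validation rejects broken partitions", {
  e <- default_catphan_ramp()$entries
  e$mu_low[1] <- 0.01
  expect_error(material_ramp(e), "start at 0")
  e <- default_catphan_ramp()$entries
  e$mu_high[nrow(e)] <- 5
  expect_error(material_ramp(e), "unbounded")
  e <- default_catphan_ramp()$entries
  e$mu_high[3] <- e$mu_high[3] * 1.1
  expect_error(material_ramp(e), "contiguous")
})

test_that("volume_from_mu assigns materials and densities voxelwise", {
  ramp <- default_catphan_ramp()
  z <- array(0, dim = c(3, 3, 2))
  ph <- volume_from_mu(z, ramp, 0.1)
  expect_true(all(ph$materials[ph$material_index] == "Vacuum"))
  expect_true(all(ph$density == 0))

  w <- array(0.243, dim = c(3, 3, 2))
  ph <- volume_from_mu(w, ramp, 0.1)
  expect_true(all(ph$materials[ph$material_index] == "Water"))
  expect_equal(max(abs(ph$density - 1.0)), 0)

  two <- array(c(0.1, 0.45), dim = c(2, 1, 1))
  ph <- volume_from_mu(two, ramp, 0.1)
  expect_equal(ph$materials[ph$material_index[, 1, 1]], c("PMP", "Teflon"))
  expect_equal(as.numeric(ph$density),
               c(0.1 / 0.178 * 0.83, 0.45 / 0.485 * 2.10), tolerance = 1e-12)

  neg <- array(c(-0.01, 0.243), dim = c(2, 1, 1))
  expect_message(ph <- volume_from_mu(neg, ramp, 0.1), "clamped")
  expect_equal(ph$density[1, 1, 1], 0)
  bad <- array(c(NaN, 0.2), dim = c(2, 1, 1))
  expect_error(volume_from_mu(bad, ramp, 0.1), "non-finite")
})

test_that("volume_from_mu round-trips a noiseless assignment", {
  ramp <- default_catphan_ramp()
  mu0 <- array(c(0.15, 0.2, 0.243, 0.31, 0.5, 0.0006), dim = c(6, 1, 1))
  ph <- volume_from_mu(mu0, ramp, 0.1)
  # forward: density / rho_mat * mu_mat recovers the input attenuation
  e <- ramp$entries
  mu_back <- e$mu_mat[ph$material_index] * ph$density /
    pmax(e$rho_mat[ph$material_index], 1e-300)
  dim(mu_back) <- dim(mu0)
  ph2 <- volume_from_mu(mu_back, ramp, 0.1)
  expect_identical(ph2$material_index, ph$material_index)
})

test_that("water/air phantom geometry", {
  ph <- make_water_air_phantom(voxel_size = 0.2, n = 128)
  mats <- ph$materials
  d <- dim(ph$density)
  ctr <- d %/% 2
  expect_equal(mats[ph$material_index[ctr[1], ctr[2], ctr[3]]], "Air")
  ix <- ctr[1] + round(5 / 0.2)
  expect_equal(mats[ph$material_index[ix, ctr[2], ctr[3]]], "Water")
  # discretized volume matches the analytic cylinder volume within 2%
  filled <- sum(mats[ph$material_index] %in% c("Water", "Air"))
  expect_equal(filled * 0.2^3, pi * 10^2 * 20, tolerance = 0.02)
  # degenerate cavity
  ph0 <- make_water_air_phantom(cavity_diameter = 0, voxel_size = 0.4, n = 64)
  expect_false("Air" %in% ph0$materials[unique(as.integer(ph0$material_index))])
  expect_error(make_water_air_phantom(cavity_diameter = 30), "fit")
})

test_that("material_mu interpolates the embedded tables", {
  # liquid water at 60 keV, published tabulation: 0.2059 1/cm
  expect_equal(material_mu("Water", 60), 0.2059, tolerance = 0.01)
  # identity at tabulated nodes
  cat <- material_catalog()
  tab <- cat$Teflon$xs_table
  expect_equal(material_mu("Teflon", 80),
               tab$total[tab$energy_kev == 80] * 2.10, tolerance = 1e-12)
  # linearity in density
  expect_equal(material_mu("Water", 75, density = 2),
               2 * material_mu("Water", 75), tolerance = 1e-12)
  expect_error(material_mu("Water", 5), "range")
  expect_error(material_mu("Water", 200), "range")
})

test_that("cross-section interpolation error < 1% at grid midpoints", {
  for (i in seq_len(nrow(xs_midpoint_reference))) {
    row <- xs_midpoint_reference[i, ]
    m <- material_catalog()[[row$material]]
    got <- material_mu(m, row$energy) / m$rho_nominal
    expect_equal(got, row$total, tolerance = 0.01)
  }
})

test_that("material validation enforces invariants", {
  tab <- material_catalog()$Water$xs_table
  expect_error(material("x", -1, 1, tab), "non-negative")
  bad <- tab; bad$total <- bad$total * 1.05
  expect_error(material("x", 0.2, 1, bad), "1%")
  bad <- tab; bad$energy_kev[2] <- bad$energy_kev[1]
  expect_error(material("x", 0.2, 1, bad), "increasing")
})
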