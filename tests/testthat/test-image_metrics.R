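test_that("HU conversion is linear with water at 1024", {
  v <- array(c(0.2059, 0, 0.2059 / 2), dim = c(3, 1, 1))
  hu <- to_hu(v, mu_water = 0.2059)
  expect_equal(as.numeric(hu), c(1024, 0, 512))
  rv <- recon_volume(v, 0.1, c(0, 0, 0), hu_scale = 0.2059)
  expect_equal(as.numeric(to_hu(rv)), c(1024, 0, 512))
  expect_error(to_hu(v, mu_water = 0))
})

test_that("roi_stats computes population statistics over a circle", {
  vol <- array(5, dim = c(64, 64, 3))
  roi <- roi_spec(c(32, 32), radius = 8, slice = 2, label = "x")
  st <- roi_stats(vol, roi)
  expect_equal(st$mean, 5)
  expect_equal(st$sd, 0)
  # radius chosen so the circle holds ~225 voxels (the published ROI size)
  r225 <- sqrt(225 / pi)
  st2 <- roi_stats(vol, roi_spec(c(32, 32), r225, 2))
  expect_equal(st2$n, 225, tolerance = 0.03)
  # two-valued region in equal counts: mean 1, population SD 1
  vol2 <- array(rep(c(0, 2), each = 32), dim = c(64, 64, 1))
  stats2 <- roi_stats(vol2, roi_spec(c(32.5, 32), 10.1, 1))
  expect_equal(stats2$mean, 1, tolerance = 0.05)
  expect_equal(stats2$sd, 1, tolerance = 0.05)
  # sample SD differs by the n/(n-1) factor
  sts <- roi_stats(vol2, roi_spec(c(32.5, 32), 10.1, 1), sd_type = "sample")
  expect_gt(sts$sd, stats2$sd)
  expect_error(roi_stats(vol, roi_spec(c(2, 2), 8, 1)), "outside")
})

test_that("rmse matches its closed forms and invariances", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(5, 2), 3)
  set.seed(3)
  x <- rnorm(8); y <- rnorm(8)
  p <- sample(8)
  expect_equal(rmse(x[p], y[p]), rmse(x, y))
  expect_equal(rmse(3 * x, 3 * y), 3 * rmse(x, y))
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("cnr matches its definition and symmetries", {
  a <- list(mean = 10, sd = sqrt(2)); b <- list(mean = 6, sd = sqrt(2))
  expect_equal(cnr(a, b), 2)
  expect_equal(cnr(b, a), 2)
  expect_equal(cnr(a, a), 0)
  # invariant under common offset; scales as 1 under joint affine scaling
  a2 <- list(mean = 110, sd = sqrt(2)); b2 <- list(mean = 106, sd = sqrt(2))
  expect_equal(cnr(a2, b2), cnr(a, b))
  a3 <- list(mean = 30, sd = 3 * sqrt(2)); b3 <- list(mean = 18, sd = 3 * sqrt(2))
  expect_equal(cnr(a3, b3), cnr(a, b))
  expect_error(cnr(list(mean = 1, sd = 0), list(mean = 2, sd = 0)),
               "undefined")
})

test_that("published ROI table reproduces the summary metrics", {
  tab <- catphan_roi_table()
  rep <- metrics_report_from_stats(tab, reference_label = "pCT",
                                   exclude = c("Air1", "Air2"))
  s <- rep$summary
  expect_equal(s$rmse[s$recon == "raw"], 175.8, tolerance = 0.2 / 175.8)
  expect_equal(s$rmse[s$recon == "corrected"], 65.3, tolerance = 0.2 / 65.3)
  expect_equal(s$rmse[s$recon == "varian"], 47.7, tolerance = 0.2 / 47.7)
  expect_equal(s$rmse_excl[s$recon == "corrected"], 34.2,
               tolerance = 0.2 / 34.2)
  expect_equal(s$rmse_excl[s$recon == "varian"], 50.4, tolerance = 0.2 / 50.4)
  expect_equal(s$mean_cnr[s$recon == "raw"], 12.5, tolerance = 0.1 / 12.5)
  expect_equal(s$mean_cnr[s$recon == "corrected"], 14.8,
               tolerance = 0.1 / 14.8)
  expect_equal(s$mean_cnr[s$recon == "varian"], 13.0, tolerance = 0.1 / 13.0)
  # excluding air changes only the excluded-RMSE column
  rep2 <- metrics_report_from_stats(tab, "pCT")
  expect_equal(rep2$summary$rmse, s$rmse)
  expect_equal(rep2$summary$mean_cnr, s$mean_cnr)
  expect_false(isTRUE(all.equal(rep2$summary$rmse_excl, s$rmse_excl)))
  # the recomputed dhu match the printed rows
  per <- rep$per_roi
  expect_equal(per$dhu[per$recon == "raw"],
               tab$dhu[tab$recon == "raw"])
  expect_error(metrics_report_from_stats(tab, "nope"), "missing")
})

test_that("hu_cross_normalize rescales to the reference water ROI", {
  set.seed(4)
  ref <- array(1000 + rnorm(64 * 64 * 2, sd = 5), dim = c(64, 64, 2))
  roi <- roi_spec(c(32, 32), 8, 1, "Water")
  expect_equal(hu_cross_normalize(ref, ref, roi), ref)
  vol <- 2 * ref
  out <- hu_cross_normalize(vol, ref, roi)
  expect_equal(out, ref, tolerance = 1e-12)
  # noisy pair: factor equals the ratio of ROI means within standard error
  vol2 <- 1.3 * ref + array(rnorm(length(ref), sd = 2), dim = dim(ref))
  out2 <- hu_cross_normalize(vol2, ref, roi)
  expect_equal(roi_stats(out2, roi)$mean, roi_stats(ref, roi)$mean,
               tolerance = 1e-9)
})

test_that("metrics_report computes stats from volumes", {
  set.seed(9)
  mk <- function(mu1, mu2) {
    v <- array(1000 + rnorm(48 * 48 * 1, 0, 3), dim = c(48, 48, 1))
    v[10:16, 10:16, 1] <- mu1 + rnorm(49, 0, 3)
    v[30:36, 30:36, 1] <- mu2 + rnorm(49, 0, 3)
    v
  }
  vols <- list(pCT = mk(800, 1300), cbct = mk(850, 1250))
  rois <- list(roi_spec(c(13, 13), 3, 1, "A"), roi_spec(c(33, 33), 3, 1, "B"))
  rep <- metrics_report(vols, rois, "pCT", background_offset = c(10, 0))
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep$per_roi), 4)
  dh <- rep$per_roi$dhu[rep$per_roi$recon == "cbct"]
  expect_equal(dh, c(50, -50), tolerance = 0.2)
  expect_true(all(is.finite(rep$summary$mean_cnr)))
  expect_error(metrics_report(vols, rois, "missing"), "reference")
})
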