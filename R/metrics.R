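#' Circular region of interest
#'
#' @param center voxel coordinates `(i, j)` of the ROI center (1-based, in
#'   the slice plane).
#' @param radius ROI radius in voxels.
#' @param slice slice index (third array dimension).
#' @param label material label for the ROI.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(center, radius, slice, label = "") {
  stopifnot(length(center) == 2, radius > 0, slice >= 1)
  structure(list(center = center, radius = radius, slice = as.integer(slice),
                 label = label),
            class = "roi_spec")
}

#' Convert attenuation to CT numbers
#'
#' Linear CT-number scale with water at 1024 HU and vacuum at 0:
#' `HU = 1024 * mu / mu_water`.
#'
#' @param volume a [recon_volume] or numeric array of attenuation (1/cm).
#' @param mu_water water attenuation defining 1024 HU (defaults to the
#'   volume's `hu_scale`).
#' @return numeric array of CT numbers.
#' @export
to_hu <- function(volume, mu_water = NULL) {
  if (inherits(volume, "recon_volume")) {
    if (is.null(mu_water)) mu_water <- volume$hu_scale
    volume <- volume$mu
  }
  if (is.null(mu_water) || mu_water <= 0) stop("mu_water must be positive")
  1024 * volume / mu_water
}

.roi_index <- function(vol_dim, roi) {
  ii <- seq_len(vol_dim[1]); jj <- seq_len(vol_dim[2])
  m <- outer((ii - roi$center[1])^2, (jj - roi$center[2])^2, "+") <=
    roi$radius^2
  if (roi$slice < 1 || roi$slice > vol_dim[3] ||
      roi$center[1] - roi$radius < 1 || roi$center[1] + roi$radius > vol_dim[1] ||
      roi$center[2] - roi$radius < 1 || roi$center[2] + roi$radius > vol_dim[2])
    stop("ROI extends outside the volume")
  which(m)
}

#' ROI mean and standard deviation
#'
#' Population (n-denominator) standard deviation by default, switchable to
#' the sample estimator.
#'
#' @param volume 3D numeric array (HU).
#' @param roi a [roi_spec].
#' @param sd_type `"population"` or `"sample"`.
#' @return list with `mean`, `sd`, `n` (class `roi_stats`).
#' @export
roi_stats <- function(volume, roi, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  idx <- .roi_index(dim(volume), roi)
  sl <- volume[, , roi$slice]
  vals <- sl[idx]
  n <- length(vals)
  s2 <- stats::var(vals)
  if (sd_type == "population") s2 <- s2 * (n - 1) / n
  structure(list(mean = mean(vals), sd = sqrt(max(s2, 0)), n = n,
                 label = roi$label),
            class = "roi_stats")
}

#' Root-mean-square error of ROI means
#'
#' `RMSE = sqrt(mean((mu_i - mu_i_ref)^2))` over paired ROI mean CT
#' numbers.
#'
#' @param means CT numbers, HU.
#' @param ref_means reference CT numbers, HU (same length).
#' @return RMSE in HU.
#' @export
rmse <- function(means, ref_means) {
  if (length(means) != length(ref_means) || length(means) < 1)
    stop("means and ref_means must have equal length >= 1")
  sqrt(mean((means - ref_means)^2))
}

#' Contrast-to-noise ratio between two ROIs
#'
#' `CNR = |mu_A - mu_B| / sqrt(sd_A^2 + sd_B^2)`; symmetric in its
#' arguments.
#'
#' @param a,b `roi_stats` objects (or lists with `mean` and `sd`).
#' @return dimensionless CNR.
#' @export
cnr <- function(a, b) {
  s2 <- a$sd^2 + b$sd^2
  if (s2 <= 0) stop("CNR undefined: both standard deviations are zero")
  abs(a$mean - b$mean) / sqrt(s2)
}

#' Cross-scanner CT-number normalization
#'
#' Rescales a volume by the single multiplicative factor that makes its
#' water-ROI mean agree with the reference volume's.
#'
#' @param volume,reference 3D HU arrays.
#' @param water_roi a [roi_spec] valid in both volumes.
#' @return rescaled `volume`.
#' @export
hu_cross_normalize <- function(volume, reference, water_roi) {
  mv <- roi_stats(volume, water_roi)$mean
  mr <- roi_stats(reference, water_roi)$mean
  if (abs(mv) < 1e-12) stop("zero ROI mean in volume; cannot normalize")
  volume * (mr / mv)
}

#' Image-quality report from precomputed ROI statistics
#'
#' Assembles the summary metrics of a sensitometry analysis from a table of
#' per-ROI statistics: CT-number differences to the reference scan, overall
#' RMSE (with and without excluded ROIs), mean SD, and mean CNR.
#'
#' @param stats data.frame with columns `material`, `recon`, `mean`, `sd`,
#'   `cnr` (and optionally `dhu`).
#' @param reference_label value of `recon` used as reference (e.g. the
#'   planning CT).
#' @param exclude material labels excluded from the secondary RMSE (e.g.
#'   air, whose CT numbers are dominated by beam hardening).
#' @return object of class `metrics_report`: list with `per_roi`
#'   (data.frame with `dhu` columns) and `summary` (per-recon `rmse`,
#'   `rmse_excl`, `mean_sd`, `mean_cnr`).
#' @export
metrics_report_from_stats <- function(stats, reference_label = "pCT",
                                      exclude = character()) {
  stopifnot(all(c("material", "recon", "mean", "sd", "cnr") %in% names(stats)))
  if (!reference_label %in% stats$recon)
    stop("reference recon '", reference_label, "' missing from stats")
  ref <- stats[stats$recon == reference_label, ]
  recons <- unique(stats$recon)
  per <- stats
  per$dhu <- NA_real_
  for (rc in recons) {
    sel <- per$recon == rc
    m <- match(per$material[sel], ref$material)
    per$dhu[sel] <- per$mean[sel] - ref$mean[m]
  }
  summ <- do.call(rbind, lapply(recons, function(rc) {
    s <- per[per$recon == rc, ]
    s <- s[match(ref$material, s$material), ]
    keep <- !(s$material %in% exclude)
    data.frame(recon = rc,
               rmse = if (rc == reference_label) NA_real_
                      else rmse(s$mean, ref$mean),
               rmse_excl = if (rc == reference_label) NA_real_
                           else rmse(s$mean[keep], ref$mean[keep]),
               mean_sd = mean(s$sd),
               mean_cnr = mean(s$cnr))
  }))
  structure(list(per_roi = per, summary = summ,
                 reference = reference_label, excluded = exclude),
            class = "metrics_report")
}

#' Image-quality report from reconstructed volumes
#'
#' Computes per-ROI statistics for each named HU volume, with CNR referenced
#' to a background ROI displaced from each insert by `background_offset`
#' voxels, then assembles the summary via [metrics_report_from_stats()].
#'
#' @param volumes named list of 3D HU arrays (one name must equal
#'   `reference_label`).
#' @param rois list of [roi_spec]s (labels identify the materials).
#' @param reference_label name of the reference volume.
#' @param background_offset integer `(di, dj)` displacement of the
#'   background ROI relative to each insert ROI.
#' @param exclude material labels excluded from the secondary RMSE.
#' @return a `metrics_report`.
#' @export
metrics_report <- function(volumes, rois, reference_label,
                           background_offset = c(0, 0), exclude = character()) {
  if (!reference_label %in% names(volumes))
    stop("missing reference volume '", reference_label, "'")
  rows <- list()
  for (vn in names(volumes)) {
    v <- volumes[[vn]]
    for (roi in rois) {
      st <- roi_stats(v, roi)
      bg_roi <- roi
      bg_roi$center <- roi$center + background_offset
      cn <- if (all(background_offset == 0)) NA_real_
            else cnr(st, roi_stats(v, bg_roi))
      rows[[length(rows) + 1]] <-
        data.frame(material = roi$label, recon = vn, mean = st$mean,
                   sd = st$sd, cnr = cn)
    }
  }
  metrics_report_from_stats(do.call(rbind, rows), reference_label, exclude)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report (reference:", x$reference, ")\n")
  s <- x$summary
  s$rmse <- round(s$rmse, 1); s$rmse_excl <- round(s$rmse_excl, 1)
  s$mean_sd <- round(s$mean_sd, 1); s$mean_cnr <- round(s$mean_cnr, 1)
  print(s, row.names = FALSE)
  invisible(x)
}
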