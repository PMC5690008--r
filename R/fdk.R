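#' Log-domain projection
#'
#' Line-integral-valued detector raster: the air-normalized measurement
#' `r = ln(B/R)`, a simulated counterpart, or a scatter-corrected `p`.
#'
#' @param pixels finite numeric matrix.
#' @param angle projection angle, degrees.
#' @param kind one of `"raw"`, `"simulated"`, `"corrected"`.
#' @return object of class `log_projection`.
#' @export
log_projection <- function(pixels, angle, kind = c("raw", "simulated",
                                                   "corrected")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(pixels))
  if (any(!is.finite(pixels))) stop("log projection must be finite")
  structure(list(pixels = pixels, angle = angle, kind = kind),
            class = "log_projection")
}

#' Reconstructed attenuation volume
#'
#' @param mu 3D array of linear attenuation coefficients, 1/cm.
#' @param voxel_size length-3 numeric, cm.
#' @param origin grid corner, cm.
#' @param hu_scale attenuation value mapped to 1024 HU (water), 1/cm.
#' @return object of class `recon_volume`.
#' @export
recon_volume <- function(mu, voxel_size, origin, hu_scale) {
  stopifnot(length(dim(mu)) == 3, all(is.finite(mu)), hu_scale > 0)
  voxel_size <- rep(voxel_size, length.out = 3)
  stopifnot(all(voxel_size > 0))
  structure(list(mu = mu, voxel_size = voxel_size, origin = origin,
                 hu_scale = hu_scale),
            class = "recon_volume")
}

# 3x3 (or k x k) median filter with edge replication
.median_filter <- function(img, k = 3) {
  h <- k %/% 2
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0, nr + 2 * h, nc + 2 * h)
  pad[h + seq_len(nr), h + seq_len(nc)] <- img
  pad[seq_len(h), ] <- pad[rep(h + 1, h), ]
  pad[nr + h + seq_len(h), ] <- pad[rep(nr + h, h), ]
  pad[, seq_len(h)] <- pad[, rep(h + 1, h)]
  pad[, nc + h + seq_len(h)] <- pad[, rep(nc + h, h)]
  stk <- array(0, dim = c(nr, nc, k * k))
  m <- 1
  for (dj in -h:h) for (di in -h:h) {
    stk[, , m] <- pad[h + seq_len(nr) + di, h + seq_len(nc) + dj]
    m <- m + 1
  }
  apply(stk, c(1, 2), stats::median)
}

#' Preprocess a raw projection
#'
#' Normalizes pixel values to the X-ray tube output monitor reading, then
#' smooths with a median filter (default 3x3).
#'
#' @param raw a [projection_image].
#' @param monitor_value positive monitor (output chamber) reading.
#' @param median_size odd median window size; 1 disables filtering.
#' @return preprocessed [projection_image].
#' @export
preprocess <- function(raw, monitor_value, median_size = 3) {
  stopifnot(inherits(raw, "projection_image"))
  if (monitor_value <= 0) stop("monitor_value must be positive")
  px <- raw$pixels / monitor_value
  if (median_size > 1) px <- .median_filter(px, median_size)
  projection_image(px, raw$component, raw$angle, raw$rel_uncertainty)
}

#' Air-normalized log projection
#'
#' Computes `r = ln(B/R)` elementwise. Total-signal pixels below
#' `floor_frac * max(B)` are floored to that value first (Monte Carlo zeros
#' must not produce infinities); the flooring count is reported via a
#' message.
#'
#' @param R total-signal [projection_image].
#' @param B blank-scan [projection_image] of the same shape.
#' @param floor_frac flooring threshold as a fraction of `max(B)`.
#' @return [log_projection] of kind `"raw"`.
#' @export
air_normalize <- function(R, B, floor_frac = 1e-6) {
  stopifnot(inherits(R, "projection_image"), inherits(B, "projection_image"),
            identical(dim(R$pixels), dim(B$pixels)))
  b <- B$pixels
  if (any(b <= 0)) stop(sum(b <= 0), " non-positive blank pixels")
  fl <- floor_frac * max(b)
  r <- pmax(R$pixels, fl)
  nfl <- sum(R$pixels < fl)
  if (nfl > 0) message(nfl, " pixels floored before log transform")
  log_projection(log(b / r), R$angle, "raw")
}

# smooth end taper used by the redundancy window (raised cosine over width f)
.arc_taper <- function(t, arc_len, f) {
  w <- rep(1, length(t))
  lo <- t < f
  w[lo] <- 0.5 - 0.5 * cos(pi * t[lo] / f)
  hi <- t > arc_len - f
  w[hi] <- 0.5 - 0.5 * cos(pi * (arc_len - t[hi]) / f)
  w[t < 0 | t > arc_len] <- 0
  w
}

#' Redundancy weight of a single ray
#'
#' Weight of the ray leaving the source at gantry angle `lambda_deg` with
#' in-plane fan angle `gamma_deg`, under a smooth (raised-cosine feathered)
#' sinogram window: rays measured twice across the arc split their weight so
#' that the two replicates sum to exactly 1; rays measured once get weight
#' 1.
#'
#' @param geometry a [cone_beam_geometry].
#' @param lambda_deg gantry angle(s), degrees.
#' @param gamma_deg signed fan angle(s), degrees.
#' @param feather_deg feather width of the taper, degrees (default: half
#'   fan angle).
#' @return weights in `[0, 1]`.
#' @export
arc_ray_weight <- function(geometry, lambda_deg, gamma_deg,
                           feather_deg = NULL) {
  L <- geometry$arc_extent
  if (is.null(feather_deg)) feather_deg <- half_fan_angle(geometry)
  feather_deg <- min(feather_deg, L / 4)
  t <- (lambda_deg - geometry$arc_start) %% 360
  tc <- (t + 180 + 2 * gamma_deg) %% 360
  s <- .arc_taper(t, L, feather_deg)
  sc <- .arc_taper(tc, L, feather_deg)
  sc[tc >= L] <- NA  # conjugate not measured
  w <- ifelse(is.na(sc), 1, ifelse(s + sc > 0, s / (s + sc), 0.5))
  pmin(pmax(w, 0), 1)
}

#' Partial-arc redundancy weights
#'
#' Per-(detector column, angle) weights of the smooth sinogram window
#' applied before filtering in partial-arc FDK reconstruction. Requires
#' `arc_extent >= 180 + full fan angle` (a short-scan-complete arc).
#'
#' @param geometry a [cone_beam_geometry].
#' @param feather_deg feather width, degrees.
#' @return `nu x n_projections` matrix of weights in `[0, 1]`.
#' @export
partial_arc_weights <- function(geometry, feather_deg = NULL) {
  L <- geometry$arc_extent
  if (L < 180 + 2 * half_fan_angle(geometry) - 1e-9)
    stop("arc too short: need at least 180 degrees plus the full fan angle")
  nu <- geometry$det_pixels[1]
  du_virt <- geometry$det_size[1] / nu * geometry$sad / geometry$sdd
  u <- ((seq_len(nu) - 0.5) - nu / 2) * du_virt
  gam <- atan2(u, geometry$sad) * 180 / pi
  ang <- arc_angles(geometry)
  W <- matrix(0, nu, length(ang))
  for (a in seq_along(ang))
    W[, a] <- arc_ray_weight(geometry, ang[a], gam, feather_deg)
  W
}

#' FDK filtered backprojection
#'
#' Feldkamp-Davis-Kress cone-beam reconstruction from log projections:
#' cosine weighting, partial-arc redundancy weighting, row-wise convolution
#' with the discrete Shepp-Logan kernel on the virtual (isocenter-plane)
#' detector, and distance-weighted voxel backprojection.
#'
#' @param projections list of [log_projection]s, one per angle of the
#'   geometry's schedule (any order; matched by angle).
#' @param geometry a [cone_beam_geometry].
#' @param recon_grid list with `dims` (length-3 integer), `voxel_size`
#'   (cm), and optionally `origin` (cm; default centers the grid).
#' @param feather_deg feather width of the arc window, degrees.
#' @param hu_scale attenuation mapped to 1024 HU in the output volume,
#'   1/cm (default: water at 60 keV).
#' @return a [recon_volume] (attenuation in 1/cm).
#' @export
fdk_reconstruct <- function(projections, geometry, recon_grid,
                            feather_deg = NULL, hu_scale = NULL) {
  ang <- arc_angles(geometry)
  na <- length(ang)
  got <- vapply(projections, function(p) p$angle, numeric(1))
  ord <- match(round(ang, 9), round(got, 9))
  if (any(is.na(ord)))
    stop("missing projections at angles: ",
         paste(ang[is.na(ord)], collapse = ", "))
  projections <- projections[ord]
  nu <- geometry$det_pixels[1]; nv <- geometry$det_pixels[2]
  mag <- geometry$sad / geometry$sdd
  du <- geometry$det_size[1] / nu * mag
  dv <- geometry$det_size[2] / nv * mag
  # cosine weights on the virtual detector
  u <- ((seq_len(nu) - 0.5) - nu / 2) * du
  v <- ((seq_len(nv) - 0.5) - nv / 2) * dv
  cosw <- geometry$sad / sqrt(geometry$sad^2 + outer(u^2, v^2, "+"))
  if (geometry$arc_extent < 360) {
    aw <- partial_arc_weights(geometry, feather_deg)
  } else {
    aw <- matrix(NA_real_, nu, na)
    ang_gam <- atan2(u, geometry$sad) * 180 / pi
    for (a in seq_len(na))
      aw[, a] <- arc_ray_weight(geometry, ang[a], ang_gam, feather_deg)
  }
  stk <- numeric(nu * nv * na)
  for (a in seq_len(na)) {
    p <- projections[[a]]$pixels
    if (!all(dim(p) == c(nu, nv)))
      stop("projection dimensions do not match the geometry")
    stk[(a - 1) * nu * nv + seq_len(nu * nv)] <- p * cosw * aw[, a]
  }
  filt <- cpp_fdk_filter(stk, nu, nv, na, du)
  dims <- as.integer(recon_grid$dims)
  vox <- rep(recon_grid$voxel_size, length.out = 3)
  origin <- if (!is.null(recon_grid$origin)) recon_grid$origin else
    -dims * vox / 2
  dl <- geometry$arc_extent / na * pi / 180
  vol <- cpp_fdk_backproject(filt, nu, nv, na, ang * pi / 180,
                             geometry$sad, du, dv, dims, vox, origin, dl)
  dim(vol) <- dims
  if (is.null(hu_scale)) hu_scale <- material_mu("Water", 60)
  recon_volume(vol, vox, origin, hu_scale)
}

#' Resample an image or volume between grids
#'
#' Bicubic (Catmull-Rom) interpolation for upsampling smooth projections to
#' the full detector grid, and block averaging for integer-factor
#' downsampling of reconstructed slices. Both preserve constants exactly;
#' block averaging preserves the mean exactly.
#'
#' @param x numeric matrix, [projection_image], or 3D array.
#' @param target integer target dimensions (length 2 for images; for 3D
#'   arrays the third dimension is kept).
#' @param method `"bicubic"` or `"block_average"`.
#' @return resampled object of the same type.
#' @export
resample <- function(x, target, method = c("bicubic", "block_average")) {
  method <- match.arg(method)
  if (inherits(x, "projection_image")) {
    px <- resample(x$pixels, target, method)
    ru <- if (!is.null(x$rel_uncertainty))
      resample(x$rel_uncertainty, target, method) else NULL
    if (!is.null(ru)) ru <- pmax(ru, 0)
    return(projection_image(pmax(px, 0), x$component, x$angle, ru))
  }
  if (is.matrix(x)) {
    if (all(dim(x) == target)) return(x)
    if (method == "bicubic") return(cpp_bicubic(x, target[1], target[2]))
    f <- dim(x) / target
    if (any(f != round(f)) || any(f < 1))
      stop("block_average needs integer downsampling factors")
    arr <- array(x, dim = c(f[1], target[1], f[2], target[2]))
    return(apply(arr, c(2, 4), mean))
  }
  if (length(dim(x)) == 3) {
    out <- array(0, dim = c(target[1], target[2], dim(x)[3]))
    for (k in seq_len(dim(x)[3]))
      out[, , k] <- resample(x[, , k], target[1:2], method)
    return(out)
  }
  stop("unsupported input type")
}
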