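# Independent oracles used across test files. These deliberately avoid the
# package's Siddon/FDK code paths.

# closed-form line integrals through an infinite uniform cylinder of radius
# R_cyl (axis = z, centered at origin): analytic log projections
analytic_cylinder_logproj <- function(geometry, mu, R_cyl) {
  lapply(arc_angles(geometry), function(a) {
    fr <- cbctscatter:::.det_frame(geometry, a)
    iu <- matrix(seq_len(fr$nu) - 0.5, fr$nu, fr$nv)
    iv <- matrix(rep(seq_len(fr$nv) - 0.5, each = fr$nu), fr$nu, fr$nv)
    px <- fr$corner[1] + iu * fr$du * fr$uhat[1] + iv * fr$dv * fr$vhat[1]
    py <- fr$corner[2] + iu * fr$du * fr$uhat[2] + iv * fr$dv * fr$vhat[2]
    pz <- fr$corner[3] + iu * fr$du * fr$uhat[3] + iv * fr$dv * fr$vhat[3]
    dx <- px - fr$src[1]; dy <- py - fr$src[2]; dz <- pz - fr$src[3]
    nrm <- sqrt(dx^2 + dy^2 + dz^2)
    dx <- dx / nrm; dy <- dy / nrm; dz <- dz / nrm
    a2 <- dx^2 + dy^2
    b <- 2 * (fr$src[1] * dx + fr$src[2] * dy)
    c0 <- fr$src[1]^2 + fr$src[2]^2 - R_cyl^2
    disc <- b^2 - 4 * a2 * c0
    chord <- ifelse(disc > 0, sqrt(pmax(disc, 0)) / a2, 0)
    log_projection(mu * chord, a, "raw")
  })
}

# brute-force radiological path by dense ray marching (independent of the
# Siddon traversal); step in cm
march_rho_path <- function(phantom, p0, p1, step = 1e-3) {
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  n <- ceiling(len / step)
  t <- (seq_len(n) - 0.5) / n
  pts <- cbind(p0[1] + t * d[1], p0[2] + t * d[2], p0[3] + t * d[3])
  dims <- dim(phantom$density)
  i <- floor((pts[, 1] - phantom$origin[1]) / phantom$voxel_size[1]) + 1
  j <- floor((pts[, 2] - phantom$origin[2]) / phantom$voxel_size[2]) + 1
  k <- floor((pts[, 3] - phantom$origin[3]) / phantom$voxel_size[3]) + 1
  ok <- i >= 1 & i <= dims[1] & j >= 1 & j <= dims[2] & k >= 1 & k <= dims[3]
  rho <- numeric(n)
  idx <- cbind(i[ok], j[ok], k[ok])
  rho[ok] <- phantom$density[idx]
  mat <- integer(n)
  mat[ok] <- phantom$material_index[idx]
  seg <- len / n
  # rho-weighted path per material index
  out <- tapply(rho * seg, mat, sum)
  out[names(out) != "0"]
}

# small two-material slab phantom used by transport tests
tiny_slab_phantom <- function(thickness = 4, voxel = 0.25, n = 48) {
  ramp <- default_catphan_ramp()
  mats <- ramp$entries$material_name
  iv <- match("Vacuum", mats); iw <- match("Water", mats)
  idx <- array(iv, dim = c(n, n, n))
  dens <- array(0, dim = c(n, n, n))
  ctr <- (seq_len(n) - 0.5) * voxel - n * voxel / 2
  sel <- abs(ctr) <= thickness / 2
  idx[, sel, ] <- iw
  dens[, sel, ] <- 1
  voxel_phantom(idx, dens, rep(voxel, 3), rep(-n * voxel / 2, 3), mats)
}

small_geometry <- function(nu = 64, nv = 48, na = 8, arc = 360) {
  cone_beam_geometry(100, 149.88, c(39.7, 29.8), c(nu, nv),
                     arc_start = 0, arc_extent = arc, n_projections = na)
}

# frozen reference values from a dense independent tabulation (midpoints of
# the embedded 1 keV grid), total mass attenuation in cm^2/g
xs_midpoint_reference <- data.frame(
  material = rep(c("Water", "Teflon", "Delrin"), each = 3),
  energy = rep(c(15.5, 61.5, 140.5), 3),
  total = c(1.53112, 0.203586, 0.153681,
            1.90461, 0.185280, 0.133829,
            1.21786, 0.191709, 0.147130))
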