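#' Catphan-like sensitometry phantom
#'
#' A water-equivalent cylinder containing the eight sensitometry inserts of
#' the standard ramp material set (two air, PMP, LDPE, polystyrene,
#' acrylic, Delrin, Teflon) on a ring, mimicking the contrast-insert module
#' of a Catphan 600.
#'
#' @param diameter,length cylinder dimensions, cm.
#' @param insert_diameter insert diameter, cm.
#' @param insert_ring_radius radius of the insert ring, cm.
#' @param voxel_size isotropic voxel size, cm.
#' @param n voxels per axis.
#' @return a [voxel_phantom]; attribute `insert_centers` holds a data.frame
#'   of insert labels and (x, y) centers in cm.
#' @export
make_catphan_phantom <- function(diameter = 20, length = 20,
                                 insert_diameter = 1.2,
                                 insert_ring_radius = 6,
                                 voxel_size = 0.2,
                                 n = ceiling(1.25 * max(diameter, length) / voxel_size)) {
  ramp <- default_catphan_ramp()
  mats <- ramp$entries$material_name
  inserts <- c("Air", "PMP", "LDPE", "Polystyrene", "Air",
               "Acrylic", "Delrin", "Teflon")
  th <- (seq_along(inserts) - 1) * 2 * pi / length(inserts)
  cx <- insert_ring_radius * cos(th)
  cy <- insert_ring_radius * sin(th)
  ctr <- (seq_len(n) - 0.5) * voxel_size - n * voxel_size / 2
  r2 <- outer(ctr^2, ctr^2, "+")
  base <- matrix(match("Vacuum", mats), n, n)
  dens <- matrix(0, n, n)
  inside <- r2 <= (diameter / 2)^2
  base[inside] <- match("Water", mats)
  dens[inside] <- 1.0
  rho_of <- function(nm) ramp$entries$rho_mat[match(nm, mats)]
  for (i in seq_along(inserts)) {
    d2 <- outer((ctr - cx[i])^2, (ctr - cy[i])^2, "+")
    m <- d2 <= (insert_diameter / 2)^2
    base[m] <- match(inserts[i], mats)
    dens[m] <- rho_of(inserts[i])
  }
  idx <- array(match("Vacuum", mats), dim = c(n, n, n))
  den <- array(0, dim = c(n, n, n))
  for (k in seq_len(n)) {
    if (abs(ctr[k]) <= length / 2) { idx[, , k] <- base; den[, , k] <- dens }
  }
  ph <- voxel_phantom(idx, den, rep(voxel_size, 3),
                      rep(-n * voxel_size / 2, 3), mats)
  lab <- inserts
  lab[inserts == "Air"] <- c("Air1", "Air2")[cumsum(inserts == "Air")[inserts == "Air"]]
  attr(ph, "insert_centers") <- data.frame(label = lab, x = cx, y = cy)
  ph
}

#' Deterministic test fixtures
#'
#' Builds a named, seeded bundle for the two reference experiments:
#'
#' * `"water_phantom"`: the mathematical water cylinder with coaxial air
#'   cavity scanned with a monoenergetic 60 keV source over a full 360
#'   degree arc (no antiscatter grid, `beta = 1`). At `"full"` scale: 360
#'   projections, 0.1 cm voxels. At `"desk"` scale: 128^3 phantom voxels,
#'   90 projections, a 128 x 96 detector, and a scatter-free reference
#'   reconstruction for convergence testing.
#' * `"catphan_like"`: the sensitometry phantom under the clinical partial
#'   arc preset (200 degrees, 372 projections, 100 kVp spectrum,
#'   `beta = 0.5`); `"desk"` scale shrinks the grids and angle count.
#'
#' @param name `"water_phantom"` or `"catphan_like"`.
#' @param scale `"full"` or `"desk"`.
#' @param seed integer seed recorded in the bundle.
#' @param reference compute the scatter-free reference reconstruction
#'   (water phantom only; default TRUE at desk scale).
#' @return list with `phantom`, `config` (see [correction_config()]),
#'   `params`, `seed`, and optionally `reference` (a [recon_volume]).
#' @export
generate_fixture <- function(name = c("water_phantom", "catphan_like"),
                             scale = c("desk", "full"), seed = 1,
                             reference = (scale[1] == "desk" &&
                                          name[1] == "water_phantom")) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  if (name == "water_phantom") {
    desk <- scale == "desk"
    vox <- if (desk) 0.2 else 0.1
    nvox <- if (desk) 128L else 256L
    phantom <- make_water_air_phantom(voxel_size = vox, n = nvox)
    geom <- cone_beam_geometry(100, 149.88, c(39.7, 29.8),
                               if (desk) c(128L, 96L) else c(512L, 384L),
                               arc_start = 0, arc_extent = 360,
                               n_projections = if (desk) 90L else 360L)
    spec <- spectrum_mono(60)
    params <- correction_params(alpha = 0, beta = 1, max_iter = 3)
    rg <- list(dims = c(nvox, nvox, if (desk) 96L else 192L),
               voxel_size = vox)
    cfg <- correction_config(geom, spec, params, make_mono_ramp(60),
                             vrt = vrt_params(), n_histories = 1e5,
                             recon_grid = rg,
                             scoring_pixels = if (desk) c(64L, 48L)
                                              else c(256L, 192L),
                             seed = seed, replicate_projections = TRUE,
                             rmse_radius_cm = 11,
                             mu_water = material_mu("Water", 60))
    out <- list(phantom = phantom, config = cfg, params = params,
                seed = seed)
    if (reference) {
      sid <- siddon_primary(phantom, geom, spec, arc_angles(geom)[1])
      rp <- air_normalize(sid$primary, sid$blank)
      projs <- lapply(arc_angles(geom), function(a)
        log_projection(rp$pixels, a, "raw"))
      out$reference <- fdk_reconstruct(projs, geom, rg,
                                       hu_scale = cfg$mu_water)
    }
    return(out)
  }
  # catphan_like
  desk <- scale == "desk"
  vox <- if (desk) 0.2 else 0.1
  nvox <- if (desk) 128L else 256L
  phantom <- make_catphan_phantom(voxel_size = vox, n = nvox)
  geom <- cone_beam_geometry(100, 149.88, c(39.7, 29.8),
                             if (desk) c(128L, 96L) else c(1024L, 768L),
                             arc_start = 0, arc_extent = 200,
                             n_projections = if (desk) 93L else 372L)
  spec <- spectrum_kvp(100)
  params <- correction_params(alpha = 0, beta = 0.5, max_iter = 3)
  rg <- list(dims = c(nvox, nvox, if (desk) 96L else 192L), voxel_size = vox)
  cfg <- correction_config(geom, spec, params, default_catphan_ramp(),
                           vrt = vrt_params(),
                           n_histories = if (desk) 5e4 else 1e6,
                           recon_grid = rg,
                           scoring_pixels = if (desk) c(64L, 48L)
                                            else c(256L, 192L),
                           seed = seed)
  list(phantom = phantom, config = cfg, params = params, seed = seed)
}

#' Simulate the raw (scatter-contaminated) scan of a fixture
#'
#' Generates the "measured" data of a synthetic experiment: deterministic
#' primary plus smoothed Monte Carlo scatter per angle, air-normalized to
#' the analytic blank scan.
#'
#' @param fixture bundle from [generate_fixture()].
#' @param seed seed for the data-generation Monte Carlo (distinct from the
#'   correction loop's seeds).
#' @return list with `r` (raw [log_projection]s) and `B` (blank
#'   [projection_image]s), suitable for [run_correction()].
#' @export
simulate_raw_scan <- function(fixture, seed = fixture$seed + 500000) {
  cfg <- fixture$config
  sims <- .simulate_scan(fixture$phantom, cfg$geometry, cfg, seed)
  ang <- arc_angles(cfg$geometry)
  r <- vector("list", length(ang))
  for (a in seq_along(ang)) {
    tot <- projection_image(sims$P[[a]]$pixels + sims$S[[a]]$pixels, "R",
                            ang[a])
    r[[a]] <- air_normalize(tot, sims$B[[a]])
  }
  list(r = r, B = sims$B)
}
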