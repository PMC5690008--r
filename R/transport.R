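#' X-ray spectra
#'
#' `spectrum_mono()` builds a single-line spectrum. `spectrum_kvp()` builds a
#' filtered Kramers-type bremsstrahlung spectrum discretized into `n_lines`
#' energy bins: relative fluence `(kvp - E)/E`, hardened by an equivalent
#' water filtration thickness standing in for inherent tube filtration.
#' Weights are normalized to sum to 1.
#'
#' @param energy line energy, keV.
#' @return object of class `xray_spectrum` with fields `lines`
#'   (data.frame `energy`, `weight`) and `mode`.
#' @export
spectrum_mono <- function(energy) {
  stopifnot(energy >= 10, energy <= 150)
  structure(list(lines = data.frame(energy = energy, weight = 1),
                 mode = "monoenergetic"),
            class = "xray_spectrum")
}

#' @rdname spectrum_mono
#' @param kvp tube potential, kV.
#' @param n_lines number of energy bins.
#' @param filtration_cm_water equivalent water filtration, cm.
#' @export
spectrum_kvp <- function(kvp = 100, n_lines = 20, filtration_cm_water = 4) {
  stopifnot(kvp > 20, kvp <= 150)
  E <- seq(20, kvp - 2, length.out = n_lines)
  w <- (kvp - E) / E
  muw <- material_mu("Water", E)
  w <- w * exp(-muw * filtration_cm_water)
  w <- w / sum(w)
  structure(list(lines = data.frame(energy = E, weight = w),
                 mode = "sampled"),
            class = "xray_spectrum")
}

#' Mean (fluence-weighted) energy of a spectrum
#' @param spectrum an `xray_spectrum`.
#' @return keV.
#' @export
spectrum_mean_energy <- function(spectrum) {
  sum(spectrum$lines$energy * spectrum$lines$weight)
}

#' Variance-reduction parameters
#'
#' Controls for the Monte Carlo engine: after its first interaction a photon
#' is split into `n_split` daughters of weight `1/n_split`; daughters not
#' scored at the detector survive Russian roulette with probability
#' `1/rr_factor` and then carry weight `rr_factor/n_split`; subsequent
#' interactions split by `rr_factor` so that every detector-scored photon
#' carries the same weight `1/n_split`. `path_stretch` is the dimensionless
#' exponential-transform parameter (0 = off) that stretches sampled free
#' paths to favor deep interactions; `photon_cutoff` (keV) terminates
#' low-energy photons.
#'
#' @param n_split splitting number Np (>= 1).
#' @param rr_factor Russian-roulette factor Ns (>= 1).
#' @param path_stretch exponential-transform parameter, >= 0.
#' @param forced_detection score interactions at the detector analytically.
#' @param photon_cutoff transport cutoff, keV (>= 10, the table minimum).
#' @return object of class `vrt_params`.
#' @export
vrt_params <- function(n_split = 32, rr_factor = 8, path_stretch = 0,
                       forced_detection = TRUE, photon_cutoff = 10) {
  stopifnot(n_split >= 1, rr_factor >= 1, path_stretch >= 0,
            photon_cutoff >= 10)
  structure(list(n_split = as.integer(n_split),
                 rr_factor = as.integer(rr_factor),
                 path_stretch = path_stretch,
                 forced_detection = forced_detection,
                 photon_cutoff = photon_cutoff),
            class = "vrt_params")
}

#' Photon state
#'
#' @param position length-3 numeric, cm.
#' @param direction length-3 unit vector.
#' @param energy keV.
#' @param weight statistical weight, > 0.
#' @param scatter_order number of scatters undergone (0 = primary).
#' @return object of class `photon_state`.
#' @export
photon_state <- function(position, direction, energy, weight = 1,
                         scatter_order = 0) {
  stopifnot(length(position) == 3, length(direction) == 3, weight > 0,
            scatter_order >= 0)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) stop("direction must be unit norm")
  structure(list(position = position, direction = direction, energy = energy,
                 weight = weight, scatter_order = scatter_order),
            class = "photon_state")
}

# Build the cross-section matrices (nE x nmat) for a phantom's material list,
# in the order of phantom$materials. Vacuum columns are zero.
.xs_matrices <- function(materials) {
  key <- paste(materials, collapse = "|")
  cache <- .cbct_env$xs_mat_cache
  if (!is.null(cache) && identical(cache$key, key)) return(cache)
  cat <- material_catalog()
  e0 <- NULL
  tabs <- lapply(materials, function(nm) {
    m <- cat[[nm]]
    if (is.null(m)) stop("material not in catalogue: ", nm)
    m$xs_table
  })
  egrid <- NULL
  for (tb in tabs) if (!is.null(tb)) { egrid <- tb$energy_kev; break }
  if (is.null(egrid)) stop("no non-vacuum materials")
  nE <- length(egrid)
  mk <- function(col) {
    out <- matrix(0, nE, length(materials))
    for (i in seq_along(tabs))
      if (!is.null(tabs[[i]])) out[, i] <- tabs[[i]][[col]]
    out
  }
  ffx <- NULL
  for (nm in materials) {
    m <- cat[[nm]]
    if (!is.null(m$ff_table)) { ffx <- m$ff_table$x_invA; break }
  }
  ff2 <- matrix(1, length(ffx), length(materials))
  for (i in seq_along(materials)) {
    m <- cat[[materials[i]]]
    if (!is.null(m$ff_table)) ff2[, i] <- m$ff_table$ff2
  }
  res <- list(key = key, photo = mk("photo"), incoh = mk("incoh"),
              coh = mk("coh"), total = mk("total"),
              E0 = egrid[1], dE = egrid[2] - egrid[1],
              ffx = ffx, ff2 = ff2)
  .cbct_env$xs_mat_cache <- res
  res
}

.check_spectrum <- function(spectrum, xs) {
  if (nrow(spectrum$lines) == 0) stop("empty spectrum")
  emax <- xs$E0 + (nrow(xs$total) - 1) * xs$dE
  if (any(spectrum$lines$energy < xs$E0 | spectrum$lines$energy > emax))
    stop("spectrum energies outside the cross-section table")
}

#' Deterministic primary and blank projection (Siddon ray tracing)
#'
#' Traces one ray (or an `n_sub` x `n_sub` sub-sampled bundle) per detector
#' pixel through the phantom with exact voxel traversal. The blank image is
#' the unattenuated spectrum-weighted energy fluence per pixel (inverse
#' square and obliquity included); the primary applies Beer-Lambert
#' attenuation with the radiological path at each spectrum line. Both images
#' are noiseless.
#'
#' @param phantom a [voxel_phantom].
#' @param geometry a [cone_beam_geometry].
#' @param spectrum an `xray_spectrum`.
#' @param angle projection angle, degrees.
#' @param n_sub sub-rays per pixel axis (1 = pixel-center ray; larger values
#'   approximate the pixel-averaged signal).
#' @return list with [projection_image]s `primary` and `blank`.
#' @export
siddon_primary <- function(phantom, geometry, spectrum, angle, n_sub = 1) {
  xs <- .xs_matrices(phantom$materials)
  .check_spectrum(spectrum, xs)
  fr <- .det_frame(geometry, angle)
  res <- cpp_project_siddon(
    as.numeric(phantom$density), as.integer(phantom$material_index) - 1L,
    dim(phantom$density), phantom$voxel_size, phantom$origin,
    xs$photo, xs$incoh, xs$coh, xs$total, xs$E0, xs$dE,
    spectrum$lines$energy, spectrum$lines$weight,
    fr$src, fr$corner, fr$uhat, fr$vhat, fr$du, fr$dv, fr$nu, fr$nv,
    as.integer(n_sub))
  list(primary = projection_image(res$primary, "P", angle),
       blank = projection_image(res$blank, "B", angle))
}

#' Monte Carlo projection simulation
#'
#' Transports `n_histories` photon histories from the source through the
#' phantom with Woodcock (delta) tracking, interaction splitting plus
#' Russian roulette, optional path-length stretching, and forced detection:
#' at every Compton or Rayleigh interaction the analytic attenuated
#' contribution towards sampled detector points is scored. Returns unbiased
#' primary and scatter images with per-pixel relative standard errors
#' (batch estimate). Electron transport is absent; photons terminate below
#' the cutoff or on photoelectric absorption. The scatter image contains all
#' scatter orders >= 1.
#'
#' @inheritParams siddon_primary
#' @param n_histories number of photon histories (>= 1).
#' @param vrt a [vrt_params].
#' @param seed integer seed; the engine derives one independent RNG stream
#'   per history from it.
#' @param coherent include the Rayleigh channel.
#' @param n_batch number of statistical batches for uncertainty estimation.
#' @return list with [projection_image]s `primary` and `scatter` (each with
#'   `rel_uncertainty`); attributes of `scatter` carry the per-history total
#'   scatter mean and standard error (`total_mean`, `total_se`) and the
#'   range of scored relative weights (`wrel_range`, equal to `1/n_split`
#'   for every scored photon).
#' @export
simulate_projection <- function(phantom, geometry, spectrum, angle,
                                n_histories, vrt = vrt_params(), seed = 1,
                                coherent = TRUE, n_batch = 20) {
  if (n_histories < 1) stop("n_histories must be >= 1")
  xs <- .xs_matrices(phantom$materials)
  .check_spectrum(spectrum, xs)
  fr <- .det_frame(geometry, angle)
  res <- cpp_simulate_projection(
    as.numeric(phantom$density), as.integer(phantom$material_index) - 1L,
    dim(phantom$density), phantom$voxel_size, phantom$origin,
    xs$photo, xs$incoh, xs$coh, xs$total, xs$E0, xs$dE,
    xs$ffx, xs$ff2,
    spectrum$lines$energy, spectrum$lines$weight,
    fr$src, fr$corner, fr$uhat, fr$vhat, fr$du, fr$dv, fr$nu, fr$nv,
    as.integer(n_histories), vrt$n_split, vrt$rr_factor, vrt$path_stretch,
    coherent, vrt$photon_cutoff, as.numeric(seed), as.integer(n_batch))
  if (isTRUE(res$energy_increase))
    warning("photon energy increased at a scatter event (should not happen)")
  prim <- projection_image(res$primary, "P", angle,
                           rel_uncertainty = res$primary_rel)
  scat <- projection_image(res$scatter, "S", angle,
                           rel_uncertainty = res$scatter_rel)
  attr(scat, "total_mean") <- res$total_scatter_mean
  attr(scat, "total_se") <- res$total_scatter_se
  attr(scat, "wrel_range") <- c(res$scored_wrel_min, res$scored_wrel_max)
  attr(scat, "n_scored") <- res$n_scored
  list(primary = prim, scatter = scat)
}

#' Woodcock free-path sampling
#'
#' Samples free-path lengths from the homogenized majorant cross section
#' `mu_max` (distances are exponential with rate `mu_max`), using the same
#' generator as the transport engine. [accept_real()] decides whether an
#' interaction at the sampled site is real (probability
#' `local_mu / mu_max`) or fictitious (photon state unaltered).
#'
#' @param n number of samples.
#' @param mu_max majorant linear attenuation, 1/cm (> 0).
#' @param seed integer seed.
#' @return numeric vector of distances, cm.
#' @export
woodcock_free_path <- function(n, mu_max, seed = 1) {
  if (mu_max <= 0) stop("mu_max must be positive")
  cpp_woodcock_free_paths(as.integer(n), mu_max, as.numeric(seed))
}

#' @rdname woodcock_free_path
#' @param local_mu local linear attenuation at the sampled site, 1/cm,
#'   with `0 <= local_mu <= mu_max`.
#' @return logical vector: `TRUE` for a real interaction.
#' @export
accept_real <- function(local_mu, mu_max) {
  if (mu_max <= 0) stop("mu_max must be positive")
  if (any(local_mu < 0 | local_mu > mu_max))
    stop("local_mu must lie in [0, mu_max]")
  stats::runif(length(local_mu)) < local_mu / mu_max
}

#' Interaction splitting with Russian roulette
#'
#' Splits a photon into `n_split` daughters of weight `w/n_split`.
#' Detector-aimed daughters (flagged by `aimed`) keep that weight and are
#' destined for forced-detection scoring; the others undergo Russian
#' roulette with survival probability `1/rr_factor`, survivors carrying
#' weight `w * rr_factor / n_split`. The expected total daughter weight
#' equals the parent weight.
#'
#' @param photon a [photon_state].
#' @param vrt a [vrt_params] (uses `n_split`, `rr_factor`).
#' @param aimed logical vector of length `n_split` marking detector-aimed
#'   daughters (recycled; default none aimed).
#' @return list of [photon_state] daughters (possibly empty).
#' @export
split_and_roulette <- function(photon, vrt, aimed = FALSE) {
  stopifnot(inherits(photon, "photon_state"), inherits(vrt, "vrt_params"))
  np <- vrt$n_split; ns <- vrt$rr_factor
  aimed <- rep_len(aimed, np)
  out <- list()
  for (j in seq_len(np)) {
    if (aimed[j]) {
      d <- photon
      d$weight <- photon$weight / np
      d$scatter_order <- photon$scatter_order + 1L
      out[[length(out) + 1]] <- d
    } else if (stats::runif(1) < 1 / ns) {
      d <- photon
      d$weight <- photon$weight * ns / np
      d$scatter_order <- photon$scatter_order + 1L
      out[[length(out) + 1]] <- d
    }
  }
  out
}
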