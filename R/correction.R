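#' Scatter-correction parameters
#'
#' `alpha` is the relaxation parameter of the correction: a term
#' `alpha * (r - r_sim)` is added to compensate for residual differences
#' between measured and simulated attenuation. `beta` in `(0, 1]` models an
#' antiscatter grid as a multiplicative reduction of the simulated scatter:
#' it equals the ratio of scatter-to-primary ratios with and without the
#' grid (1 = no grid; about 0.5 for a 10:1 grid at SAD 100 / SDD 150).
#'
#' @param alpha relaxation parameter, dimensionless.
#' @param beta grid parameter in `(0, 1]`.
#' @param max_iter maximum number of correction iterations (>= 0).
#' @param conv_tol relative change of the inter-iteration volume RMSE below
#'   which the loop stops.
#' @return object of class `correction_params`.
#' @export
correction_params <- function(alpha = 0, beta = 0.5, max_iter = 3,
                              conv_tol = 0.01) {
  if (beta <= 0) stop("beta must be positive")
  if (max_iter < 0) stop("max_iter must be >= 0")
  if (conv_tol <= 0) stop("conv_tol must be positive")
  structure(list(alpha = alpha, beta = beta, max_iter = as.integer(max_iter),
                 conv_tol = conv_tol),
            class = "correction_params")
}

#' Antiscatter-grid parameter from scatter-to-primary ratios
#'
#' `beta = SPR_grid / SPR_no_grid`: the factor by which a grid reduces the
#' scatter-to-primary ratio. The corrected primary fraction then satisfies
#' `P / (P + beta * S) = 1 / (1 + beta * SPR)`.
#'
#' @param spr_grid scatter-to-primary ratio with the grid.
#' @param spr_no_grid scatter-to-primary ratio without the grid (> 0).
#' @return `beta`, dimensionless.
#' @export
grid_beta <- function(spr_grid, spr_no_grid) {
  if (any(spr_no_grid <= 0)) stop("spr_no_grid must be positive")
  spr_grid / spr_no_grid
}

#' Projection-domain scatter correction
#'
#' Applies the scatter correction in the log domain:
#' `p = (1 + alpha) * r - alpha * r_sim - ln(P_sim / (P_sim + beta * S_sim))`.
#' With `alpha = 0` this reduces to subtracting the simulated
#' scatter-fraction log term from the measurement.
#'
#' @param r measured [log_projection] (`r = ln(B/R)`).
#' @param r_sim simulated [log_projection] of the same scan.
#' @param P_sim simulated primary [projection_image] (> 0 after flooring).
#' @param S_sim simulated scatter [projection_image] (>= 0).
#' @param params a [correction_params].
#' @param floor_frac flooring threshold for `P_sim` as a fraction of its
#'   maximum.
#' @return corrected [log_projection] of kind `"corrected"`.
#' @export
corrected_log_projection <- function(r, r_sim, P_sim, S_sim, params,
                                     floor_frac = 1e-6) {
  stopifnot(inherits(r, "log_projection"),
            inherits(r_sim, "log_projection"),
            inherits(P_sim, "projection_image"),
            inherits(S_sim, "projection_image"),
            inherits(params, "correction_params"))
  if (!identical(dim(r$pixels), dim(P_sim$pixels)) ||
      !identical(dim(r$pixels), dim(S_sim$pixels)) ||
      !identical(dim(r$pixels), dim(r_sim$pixels)))
    stop("projection shapes do not match")
  P <- pmax(P_sim$pixels, floor_frac * max(P_sim$pixels))
  if (any(P <= 0)) stop("non-positive simulated primary after flooring")
  a <- params$alpha
  p <- (1 + a) * r$pixels - a * r_sim$pixels -
    log(P / (P + params$beta * S_sim$pixels))
  log_projection(p, r$angle, "corrected")
}

#' Iteration state of the scatter-correction loop
#'
#' @param iteration iteration index (0 = uncorrected reconstruction).
#' @param volume a [recon_volume].
#' @param corrected_projections list of corrected [log_projection]s (empty
#'   at iteration 0).
#' @param convergence_metric RMSE (HU) of the volume against the previous
#'   iteration's volume (`NA` at iteration 0).
#' @return object of class `iteration_state`.
#' @export
iteration_state <- function(iteration, volume, corrected_projections = list(),
                            convergence_metric = NA_real_) {
  stopifnot(iteration >= 0, inherits(volume, "recon_volume"))
  structure(list(iteration = as.integer(iteration), volume = volume,
                 corrected_projections = corrected_projections,
                 convergence_metric = convergence_metric),
            class = "iteration_state")
}

# r_sim = ln(B / (P + beta*S)): the simulated counterpart of the measured
# air-normalized projection, grid-adjusted through beta
.simulated_log_total <- function(B, P, S, beta, floor_frac = 1e-6) {
  tot <- P + beta * S
  tot <- pmax(tot, floor_frac * max(B))
  log(B / tot)
}

# voxel mask used for convergence/reference RMSE: cylinder of given radius
.volume_mask <- function(vol, radius_cm) {
  d <- dim(vol$mu)
  cx <- vol$origin[1] + (seq_len(d[1]) - 0.5) * vol$voxel_size[1]
  cy <- vol$origin[2] + (seq_len(d[2]) - 0.5) * vol$voxel_size[2]
  r2 <- outer(cx^2, cy^2, "+")
  array(rep(r2 <= radius_cm^2, d[3]), dim = d)
}

# RMSE between two recon volumes in HU over an optional mask
.volume_rmse_hu <- function(a, b, mask = NULL) {
  da <- 1024 * a$mu / a$hu_scale
  db <- 1024 * b$mu / b$hu_scale
  dd <- (da - db)^2
  if (!is.null(mask)) dd <- dd[mask]
  sqrt(mean(dd))
}

#' One iteration of the scatter-correction loop
#'
#' Executes a single pass of the iterative algorithm: converts the current
#' reconstruction to a material/density phantom via the ramp, simulates
#' primary (deterministic ray tracing) and scatter (Monte Carlo, smoothed,
#' upsampled to the detector grid) for every projection angle, applies the
#' projection-domain correction, and reconstructs. The convergence metric
#' is the RMSE in HU against the previous volume.
#'
#' With `config$replicate_projections = TRUE` only the first scheduled angle
#' is simulated and its projections are replicated to all angles; valid for
#' phantoms that are rotationally symmetric about the z axis.
#'
#' @param state current [iteration_state] (iteration 0 holds the
#'   uncorrected reconstruction).
#' @param raw list with the measured data: `r` = list of raw
#'   [log_projection]s, `B` = list of blank [projection_image]s, matching
#'   the geometry schedule.
#' @param config run configuration, see [correction_config()].
#' @return next [iteration_state].
#' @export
run_iteration <- function(state, raw, config) {
  stopifnot(inherits(state, "iteration_state"))
  g <- config$geometry
  params <- config$params
  ang <- arc_angles(g)
  phantom <- volume_from_mu(state$volume$mu, config$ramp,
                            state$volume$voxel_size, state$volume$origin)
  it <- state$iteration + 1L
  seed_it <- (config$seed + 1000003 * it) %% .Machine$integer.max
  sims <- .simulate_scan(phantom, g, config, seed_it)
  corrected <- vector("list", length(ang))
  for (a in seq_along(ang)) {
    r_sim_px <- .simulated_log_total(sims$B[[a]]$pixels, sims$P[[a]]$pixels,
                                     sims$S[[a]]$pixels, params$beta)
    r_sim <- log_projection(r_sim_px, ang[a], "simulated")
    corrected[[a]] <- corrected_log_projection(raw$r[[a]], r_sim,
                                               sims$P[[a]], sims$S[[a]],
                                               params)
  }
  vol <- fdk_reconstruct(corrected, g, config$recon_grid,
                         hu_scale = config$mu_water)
  metric <- .volume_rmse_hu(vol, state$volume,
                            .volume_mask(vol, config$rmse_radius_cm))
  iteration_state(it, vol, corrected, metric)
}

# simulate primary/blank (Siddon) and smoothed scatter (MC) for all angles;
# scatter is scored on the coarse scoring grid and bicubically upsampled
.simulate_scan <- function(phantom, geometry, config, seed) {
  ang <- arc_angles(geometry)
  na <- if (isTRUE(config$replicate_projections)) 1L else length(ang)
  sg <- config$scoring_geometry
  P <- vector("list", length(ang)); B <- P; S <- P
  for (a in seq_len(na)) {
    sid <- siddon_primary(phantom, geometry, config$spectrum, ang[a])
    mc <- simulate_projection(phantom, sg, config$spectrum, ang[a],
                              n_histories = config$n_histories,
                              vrt = config$vrt,
                              seed = (seed + a) %% .Machine$integer.max)
    sm <- adaptive_smooth(mc$scatter,
                          max_halfwidth = config$smooth_halfwidth %||% 16)
    up <- resample(sm, geometry$det_pixels, "bicubic")
    # scatter is energy per unit detector area times pixel area: rescale
    # from scoring-pixel area to detector-pixel area
    scale <- prod(geometry$det_size / geometry$det_pixels) /
      prod(sg$det_size / sg$det_pixels)
    up$pixels <- up$pixels * scale
    P[[a]] <- sid$primary; B[[a]] <- sid$blank; S[[a]] <- up
  }
  if (na == 1L) {
    for (a in seq_along(ang)[-1]) {
      P[[a]] <- projection_image(P[[1]]$pixels, "P", ang[a])
      B[[a]] <- projection_image(B[[1]]$pixels, "B", ang[a])
      S[[a]] <- projection_image(S[[1]]$pixels, "S", ang[a],
                                 S[[1]]$rel_uncertainty)
    }
  }
  list(P = P, B = B, S = S)
}

#' Build a run configuration for the correction loop
#'
#' @param geometry detector [cone_beam_geometry] used for reconstruction.
#' @param spectrum an `xray_spectrum`.
#' @param params a [correction_params].
#' @param ramp a [material_ramp].
#' @param vrt a [vrt_params].
#' @param n_histories Monte Carlo histories per simulated projection.
#' @param recon_grid reconstruction grid (see [fdk_reconstruct()]).
#' @param scoring_pixels scatter-scoring detector grid `(nu, nv)`; scatter
#'   is upsampled bicubically to the full grid.
#' @param seed base seed; per-iteration seeds advance deterministically.
#' @param replicate_projections simulate only the first angle and replicate
#'   (rotationally symmetric phantoms only).
#' @param rmse_radius_cm cylindrical mask radius for volume RMSE metrics.
#' @param mu_water attenuation defining 1024 HU, 1/cm.
#' @param smooth_halfwidth largest window half-width of the adaptive
#'   scatter smoother (see [adaptive_smooth()]); scatter projections are
#'   low-frequency, so the pipeline default is aggressive.
#' @return configuration list.
#' @export
correction_config <- function(geometry, spectrum, params, ramp,
                              vrt = vrt_params(), n_histories = 1e5,
                              recon_grid,
                              scoring_pixels = pmax(geometry$det_pixels %/% 2, 16L),
                              seed = 1, replicate_projections = FALSE,
                              rmse_radius_cm = NULL, mu_water = NULL,
                              smooth_halfwidth = 16) {
  sg <- cone_beam_geometry(geometry$sad, geometry$sdd, geometry$det_size,
                           scoring_pixels, geometry$arc_start,
                           geometry$arc_extent, geometry$n_projections)
  if (is.null(mu_water))
    mu_water <- sum(material_mu("Water", spectrum$lines$energy) *
                      spectrum$lines$weight)
  if (is.null(rmse_radius_cm))
    rmse_radius_cm <- 0.4 * geometry$det_size[1] * geometry$sad / geometry$sdd
  list(geometry = geometry, scoring_geometry = sg, spectrum = spectrum,
       params = params, ramp = ramp, vrt = vrt, n_histories = n_histories,
       recon_grid = recon_grid, seed = seed,
       replicate_projections = replicate_projections,
       rmse_radius_cm = rmse_radius_cm, mu_water = mu_water,
       smooth_halfwidth = smooth_halfwidth)
}

#' Run the iterative scatter correction to convergence
#'
#' Reconstructs the raw data (iteration 0), then repeats
#' reconstruct-to-phantom / simulate / correct / reconstruct until the
#' relative change of the inter-iteration volume RMSE drops below
#' `params$conv_tol` or `params$max_iter` iterations are done. If the
#' metric increases on two consecutive iterations a warning is issued and
#' the loop halts with partial results.
#'
#' @param raw measured data as in [run_iteration()].
#' @param params a [correction_params].
#' @param config configuration from [correction_config()].
#' @return list with `states` (list of [iteration_state], iteration 0
#'   first) and `trace` (data.frame: iteration, rmse_vs_prev,
#'   rmse_vs_reference if `config$reference` is set).
#' @export
run_correction <- function(raw, params, config) {
  config$params <- params
  vol0 <- fdk_reconstruct(raw$r, config$geometry, config$recon_grid,
                          hu_scale = config$mu_water)
  states <- list(iteration_state(0L, vol0))
  mask <- .volume_mask(vol0, config$rmse_radius_cm)
  ref_rmse <- function(v) {
    if (is.null(config$reference)) NA_real_
    else .volume_rmse_hu(v, config$reference, mask)
  }
  trace <- data.frame(iteration = 0L, rmse_vs_prev = NA_real_,
                      rmse_vs_reference = ref_rmse(vol0))
  nincrease <- 0
  while (states[[length(states)]]$iteration < params$max_iter) {
    prev <- states[[length(states)]]
    st <- run_iteration(prev, raw, config)
    states[[length(states) + 1]] <- st
    trace <- rbind(trace, data.frame(iteration = st$iteration,
                                     rmse_vs_prev = st$convergence_metric,
                                     rmse_vs_reference = ref_rmse(st$volume)))
    if (!is.na(prev$convergence_metric)) {
      rel <- abs(st$convergence_metric - prev$convergence_metric) /
        max(prev$convergence_metric, 1e-12)
      if (st$convergence_metric > prev$convergence_metric) {
        nincrease <- nincrease + 1
        if (nincrease >= 2) {
          warning("convergence metric increased twice; halting")
          break
        }
      } else nincrease <- 0
      if (rel < params$conv_tol) break
    }
  }
  list(states = states, trace = trace)
}
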