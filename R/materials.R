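#' Photon attenuation material
#'
#' A material couples a name with its nominal linear attenuation coefficient
#' `mu_nominal` (1/cm, at the scanner's reference spectrum), nominal mass
#' density `rho_nominal` (g/cm^3), and a table of mass attenuation
#' coefficients (cm^2/g) over 10--150 keV split into photoelectric,
#' incoherent (Compton) and coherent (Rayleigh) parts.
#'
#' @param name character label.
#' @param mu_nominal nominal linear attenuation coefficient, 1/cm.
#' @param rho_nominal nominal mass density, g/cm^3.
#' @param xs_table data.frame with columns `energy_kev`, `photo`, `incoh`,
#'   `coh`, `total` (cm^2/g), strictly increasing energies. May be `NULL`
#'   only for vacuum.
#' @param ff_table optional data.frame with columns `x_invA`, `ff2`: the
#'   squared coherent-scattering form factor, normalized to 1 at zero
#'   momentum transfer.
#' @return object of class `material`.
#' @export
material <- function(name, mu_nominal, rho_nominal, xs_table = NULL,
                     ff_table = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (mu_nominal < 0 || rho_nominal < 0)
    stop("mu_nominal and rho_nominal must be non-negative")
  if (!is.null(xs_table)) {
    stopifnot(all(c("energy_kev", "photo", "incoh", "coh", "total") %in%
                    names(xs_table)))
    if (any(diff(xs_table$energy_kev) <= 0))
      stop("xs_table energies must be strictly increasing")
    if (any(xs_table$photo < 0 | xs_table$incoh < 0 | xs_table$coh < 0))
      stop("attenuation coefficients must be non-negative")
    part <- xs_table$photo + xs_table$incoh + xs_table$coh
    rel <- abs(part - xs_table$total) / pmax(xs_table$total, 1e-300)
    if (any(rel > 0.01))
      stop("partial coefficients do not sum to total within 1%")
  }
  structure(list(name = name, mu_nominal = mu_nominal,
                 rho_nominal = rho_nominal, xs_table = xs_table,
                 ff_table = ff_table),
            class = "material")
}

.load_xs_data <- function() {
  if (!is.null(.cbct_env$xs_data)) return(.cbct_env$xs_data)
  f <- system.file("extdata", "xs_materials.csv", package = "cbctscatter")
  ffp <- system.file("extdata", "formfactor.csv", package = "cbctscatter")
  xs <- utils::read.csv(f)
  ff <- utils::read.csv(ffp)
  .cbct_env$xs_data <- list(xs = xs, ff = ff)
  .cbct_env$xs_data
}

#' Material catalogue for the Catphan-style sensitometry set
#'
#' Returns the nine materials of the standard attenuation-to-material ramp
#' (vacuum, air, PMP, LDPE, polystyrene, water, acrylic, Delrin, Teflon) with
#' embedded photon cross-section tables (10--150 keV) and coherent form
#' factors. The nominal `mu`/`rho` pairs are the ramp's reference values.
#'
#' @return named list of [material] objects.
#' @export
material_catalog <- function() {
  if (!is.null(.cbct_env$catalog)) return(.cbct_env$catalog)
  dat <- .load_xs_data()
  ramp <- default_catphan_ramp()
  out <- list()
  for (i in seq_len(nrow(ramp$entries))) {
    nm <- ramp$entries$material_name[i]
    if (nm == "Vacuum") {
      out[[nm]] <- material(nm, 0, 0, NULL, NULL)
    } else {
      xs <- dat$xs[dat$xs$material == nm, -1]
      ff <- dat$ff[dat$ff$material == nm, -1]
      out[[nm]] <- material(nm, ramp$entries$mu_mat[i],
                            ramp$entries$rho_mat[i], xs, ff)
    }
  }
  .cbct_env$catalog <- out
  out
}

#' Attenuation-to-material ramp
#'
#' An ordered set of half-open attenuation intervals `[mu_low, mu_high)`
#' partitioning `[0, Inf)`, each mapped to a material with nominal
#' `(mu_mat, rho_mat)`. Used to assign a material and density to every voxel
#' of a reconstructed attenuation volume.
#'
#' @param entries data.frame with columns `mu_low`, `mu_high`,
#'   `material_name`, `mu_mat`, `rho_mat`.
#' @return object of class `material_ramp`.
#' @export
material_ramp <- function(entries) {
  need <- c("mu_low", "mu_high", "material_name", "mu_mat", "rho_mat")
  stopifnot(all(need %in% names(entries)))
  entries <- entries[order(entries$mu_low), , drop = FALSE]
  if (entries$mu_low[1] != 0)
    stop("first ramp interval must start at 0")
  n <- nrow(entries)
  if (is.finite(entries$mu_high[n]))
    stop("last ramp interval must be unbounded above")
  if (n > 1 && any(abs(entries$mu_high[-n] - entries$mu_low[-1]) > 1e-12))
    stop("ramp intervals must be contiguous and non-overlapping")
  structure(list(entries = entries), class = "material_ramp")
}

#' Read a material ramp from CSV
#'
#' The file mirrors the ramp table layout: columns `mu_low`, `mu_high`,
#' `material_name`, `mu_mat`, `rho_mat`; `mu_high` of the last row may be
#' `Inf`. The partition property is validated on read.
#'
#' @param path CSV file path.
#' @return [material_ramp] object.
#' @export
read_ramp <- function(path) {
  material_ramp(utils::read.csv(path))
}

#' The Catphan-600 attenuation-to-material ramp
#'
#' Ramp with intervals (1/cm): vacuum below 2.5e-4, air to 0.09, PMP to
#' 0.189, LDPE to 0.209, polystyrene to 0.23, water to 0.251, acrylic to
#' 0.287, Delrin to 0.4, Teflon above. Interval ends follow the half-open
#' `[low, high)` convention.
#'
#' @return [material_ramp] object.
#' @export
default_catphan_ramp <- function() {
  f <- system.file("extdata", "ramp_catphan.csv", package = "cbctscatter")
  read_ramp(f)
}

#' Assign a material from an attenuation coefficient
#'
#' Returns the material name whose half-open ramp interval
#' `[mu_low, mu_high)` contains `mu`.
#'
#' @param mu attenuation coefficient(s), 1/cm; must be non-negative.
#' @param ramp a [material_ramp].
#' @return character vector of material names.
#' @export
assign_material <- function(mu, ramp) {
  stopifnot(inherits(ramp, "material_ramp"))
  if (any(!is.finite(mu))) stop("mu must be finite")
  if (any(mu < 0)) stop("mu must be non-negative")
  idx <- findInterval(mu, ramp$entries$mu_low)
  ramp$entries$material_name[idx]
}

#' Convert attenuation to mass density
#'
#' Fractional density scaling: `rho = mu / mu_mat * rho_mat`, so that the
#' ratio of the voxel's attenuation to the material's nominal attenuation is
#' recovered in transport by the density ratio. Vacuum maps to density 0.
#'
#' @param mu attenuation coefficient(s), 1/cm.
#' @param material a [material] object, or a material name resolved in
#'   [material_catalog()].
#' @return density in g/cm^3.
#' @export
mu_to_density <- function(mu, material) {
  if (is.character(material)) material <- material_catalog()[[material]]
  stopifnot(inherits(material, "material"))
  if (any(mu < 0)) stop("mu must be non-negative")
  if (material$mu_nominal <= 0) return(rep(0, length(mu)))
  mu / material$mu_nominal * material$rho_nominal
}

#' Voxel phantom
#'
#' A voxelized object description: per-voxel material index and mass
#' density on a regular grid. `materials` names the catalogue entry for each
#' index value.
#'
#' @param material_index 3D integer array, values in `1:length(materials)`.
#' @param density 3D numeric array (g/cm^3), same shape.
#' @param voxel_size length-3 numeric, cm.
#' @param origin position of the grid corner (corner of voxel `[1,1,1]`), cm.
#' @param materials character vector of catalogue material names.
#' @return object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(material_index, density, voxel_size, origin,
                          materials) {
  stopifnot(identical(dim(material_index), dim(density)),
            length(dim(density)) == 3)
  if (any(density < 0)) stop("density must be non-negative")
  voxel_size <- rep(voxel_size, length.out = 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (any(material_index < 1 | material_index > length(materials)))
    stop("material_index refers to uncatalogued materials")
  structure(list(material_index = material_index, density = density,
                 voxel_size = voxel_size, origin = origin,
                 materials = materials),
            class = "voxel_phantom")
}

#' Convert an attenuation volume into a voxel phantom
#'
#' Applies [assign_material()] and [mu_to_density()] voxelwise. Negative
#' attenuation values (an artifact of filtered-backprojection noise) are
#' clamped to zero before assignment; the number of clamped voxels is
#' reported via a message.
#'
#' @param mu_volume 3D array of attenuation coefficients, 1/cm.
#' @param ramp a [material_ramp].
#' @param voxel_size length-3 numeric, cm.
#' @param origin grid corner, cm; default centers the grid on the isocenter.
#' @return [voxel_phantom].
#' @export
volume_from_mu <- function(mu_volume, ramp, voxel_size,
                           origin = -dim(mu_volume) * rep(voxel_size, length.out = 3) / 2) {
  if (any(!is.finite(mu_volume))) {
    bad <- which(!is.finite(mu_volume))
    stop("non-finite attenuation at voxel indices: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  nneg <- sum(mu_volume < 0)
  if (nneg > 0) {
    message(nneg, " negative attenuation voxels clamped to 0")
    mu_volume[mu_volume < 0] <- 0
  }
  mats <- ramp$entries$material_name
  idx <- findInterval(mu_volume, ramp$entries$mu_low)
  mu_mat <- ramp$entries$mu_mat[idx]
  rho_mat <- ramp$entries$rho_mat[idx]
  dens <- ifelse(mu_mat > 0, mu_volume / mu_mat * rho_mat, 0)
  dim(idx) <- dim(mu_volume)
  dim(dens) <- dim(mu_volume)
  voxel_phantom(idx, dens, voxel_size, origin, mats)
}

#' Water cylinder phantom with a coaxial air cavity
#'
#' A homogeneous water cylinder (axis along z, centered at the isocenter)
#' containing a central cylindrical air cavity. The default dimensions are a
#' 20 cm diameter by 20 cm long cylinder with a 2 cm by 10 cm cavity.
#'
#' @param diameter,length water cylinder dimensions, cm.
#' @param cavity_diameter,cavity_length air cavity dimensions, cm; a zero
#'   cavity diameter yields a homogeneous cylinder.
#' @param voxel_size isotropic voxel size, cm.
#' @param n number of voxels per axis (cubic grid); default covers the
#'   cylinder with a margin.
#' @return [voxel_phantom] using the Catphan catalogue materials.
#' @export
make_water_air_phantom <- function(diameter = 20, length = 20,
                                   cavity_diameter = 2, cavity_length = 10,
                                   voxel_size = 0.2,
                                   n = ceiling(1.25 * max(diameter, length) / voxel_size)) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (cavity_diameter > diameter || cavity_length > length)
    stop("cavity must fit inside the cylinder")
  ramp <- default_catphan_ramp()
  mats <- ramp$entries$material_name
  iw <- match("Water", mats); ia <- match("Air", mats); iv <- match("Vacuum", mats)
  ctr <- (seq_len(n) - 0.5) * voxel_size - n * voxel_size / 2
  r2 <- outer(ctr^2, ctr^2, "+")
  inside <- r2 <= (diameter / 2)^2
  incav <- r2 <= (cavity_diameter / 2)^2
  idx <- array(iv, dim = c(n, n, n))
  dens <- array(0, dim = c(n, n, n))
  for (k in seq_len(n)) {
    z <- ctr[k]
    if (abs(z) <= length / 2) {
      sl <- matrix(iv, n, n); dn <- matrix(0, n, n)
      sl[inside] <- iw; dn[inside] <- 1.0
      if (cavity_diameter > 0 && abs(z) <= cavity_length / 2) {
        sl[incav] <- ia; dn[incav] <- 1.205e-3
      }
      idx[, , k] <- sl; dens[, , k] <- dn
    }
  }
  voxel_phantom(idx, dens, rep(voxel_size, 3),
                rep(-n * voxel_size / 2, 3), mats)
}

#' Spectrum-matched ramp for the water/air experiment
#'
#' The fractional density conversion recovers voxel attenuation exactly only
#' when the ramp's nominal attenuations are evaluated at the scan's
#' reference spectrum. This builds the three-material ramp (vacuum, air,
#' water) used for the mathematical water-phantom experiment, with `mu_mat`
#' computed from the embedded cross-section tables at the given
#' (fluence-weighted mean) energy.
#'
#' @param energy reference energy, keV.
#' @param air_water_split attenuation boundary separating air from water
#'   assignments, 1/cm.
#' @param vacuum_threshold attenuation below which a voxel is treated as
#'   vacuum, 1/cm. Air (mu ~ 2.3e-4 at 60 keV) cannot be distinguished
#'   from reconstruction noise, and its density (1.2e-3 g/cm^3) is a
#'   negligible scatterer; a threshold well above the noise floor prevents
#'   zero-clamped noise from adding net scattering mass to the simulation
#'   phantom.
#' @return a [material_ramp].
#' @export
make_mono_ramp <- function(energy = 60, air_water_split = 0.1,
                           vacuum_threshold = 0.02) {
  mu_air <- material_mu("Air", energy)
  mu_w <- material_mu("Water", energy)
  material_ramp(data.frame(
    mu_low = c(0, vacuum_threshold, air_water_split),
    mu_high = c(vacuum_threshold, air_water_split, Inf),
    material_name = c("Vacuum", "Air", "Water"),
    mu_mat = c(0, mu_air, mu_w),
    rho_mat = c(0, 1.205e-3, 1.0)))
}

#' Linear attenuation coefficient of a material at a given energy
#'
#' Log-log interpolation of the embedded total mass attenuation table,
#' multiplied by the material's nominal density.
#'
#' @param material a [material] or catalogue name.
#' @param energy photon energy, keV; must lie within the table (10--150).
#' @param density override density, g/cm^3 (defaults to `rho_nominal`).
#' @return linear attenuation coefficient, 1/cm.
#' @export
material_mu <- function(material, energy, density = NULL) {
  if (is.character(material)) material <- material_catalog()[[material]]
  stopifnot(inherits(material, "material"))
  if (is.null(material$xs_table)) return(rep(0, length(energy)))
  tab <- material$xs_table
  if (any(energy < min(tab$energy_kev) | energy > max(tab$energy_kev)))
    stop("energy outside tabulated range")
  if (is.null(density)) density <- material$rho_nominal
  lo <- exp(stats::approx(log(tab$energy_kev), log(tab$total),
                          xout = log(energy))$y)
  lo * density
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$density)
  cat("voxel_phantom:", paste(d, collapse = " x "), "voxels,",
      paste(signif(x$voxel_size, 4), collapse = " x "), "cm\n")
  cat("  materials present:",
      paste(x$materials[sort(unique(as.integer(x$material_index)))],
            collapse = ", "), "\n")
  invisible(x)
}
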