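#' Cone-beam scan geometry
#'
#' Describes a circular cone-beam scan: point source at distance `sad` from
#' the rotation axis, flat detector at distance `sdd`, and a uniform angular
#' schedule over a (possibly partial) arc.
#'
#' Frame convention: right-handed, isocenter at the origin, rotation axis =
#' z. At gantry angle 0 the source sits on +y; the detector u axis then runs
#' along +x and v along +z. The detector is centered on the source-isocenter
#' axis. Angles are projection-center angles in degrees; the schedule is
#' half-open (no duplicate sample at the arc end).
#'
#' @param sad source-to-axis distance, cm.
#' @param sdd source-to-detector distance, cm (`sdd > sad`).
#' @param det_size detector width and height, cm.
#' @param det_pixels detector pixel counts `(nu, nv)`.
#' @param arc_start first projection angle, degrees.
#' @param arc_extent arc length, degrees, in `(0, 360]`.
#' @param n_projections number of projections over the arc.
#' @return object of class `cone_beam_geometry`.
#' @export
cone_beam_geometry <- function(sad, sdd, det_size, det_pixels,
                               arc_start = 0, arc_extent = 360,
                               n_projections = 360) {
  stopifnot(sad > 0, sdd > sad, length(det_size) == 2,
            length(det_pixels) == 2)
  if (any(det_pixels < 1)) stop("det_pixels must be positive")
  if (arc_extent <= 0 || arc_extent > 360)
    stop("arc_extent must be in (0, 360]")
  if (n_projections < 1) stop("n_projections must be >= 1")
  structure(list(sad = sad, sdd = sdd, det_size = as.numeric(det_size),
                 det_pixels = as.integer(det_pixels),
                 arc_start = arc_start, arc_extent = arc_extent,
                 n_projections = as.integer(n_projections)),
            class = "cone_beam_geometry")
}

#' Clinical on-board imager geometry preset
#'
#' SAD 100 cm, SDD 149.88 cm, 39.7 x 29.8 cm flat detector with 1024 x 768
#' pixels, 372 projections over a 200 degree partial arc. With
#' `scoring_grid = TRUE` the detector is binned to the coarse Monte Carlo
#' scoring resolution of 256 x 192 pixels (1.552 x 1.552 mm^2).
#'
#' @param scoring_grid use the coarse scatter-scoring pixel grid.
#' @param arc_start first projection angle, degrees (the vendor's start
#'   angle is not publicly specified; default 0).
#' @return [cone_beam_geometry].
#' @export
make_obi_geometry <- function(scoring_grid = FALSE, arc_start = 0) {
  px <- if (scoring_grid) c(256L, 192L) else c(1024L, 768L)
  cone_beam_geometry(sad = 100, sdd = 149.88, det_size = c(39.7, 29.8),
                     det_pixels = px, arc_start = arc_start,
                     arc_extent = 200, n_projections = 372)
}

#' Projection angle schedule
#'
#' @param geometry a [cone_beam_geometry].
#' @return strictly increasing vector of `n_projections` angles (degrees),
#'   uniformly spaced over `[arc_start, arc_start + arc_extent)`.
#' @export
arc_angles <- function(geometry) {
  stopifnot(inherits(geometry, "cone_beam_geometry"))
  geometry$arc_start +
    (seq_len(geometry$n_projections) - 1) *
      geometry$arc_extent / geometry$n_projections
}

#' Half fan angle of the geometry
#'
#' Maximum in-plane angle between a detector ray and the central axis:
#' `atan((det_width / 2) / sdd)`.
#'
#' @param geometry a [cone_beam_geometry].
#' @return half fan angle in degrees.
#' @export
half_fan_angle <- function(geometry) {
  atan2(geometry$det_size[1] / 2, geometry$sdd) * 180 / pi
}

# source position, detector corner and axes for one projection angle.
# Returns everything the C++ kernels need; u,v pixel pitches in cm.
.det_frame <- function(geometry, angle_deg) {
  g <- geometry
  lam <- angle_deg * pi / 180
  src <- c(-g$sad * sin(lam), g$sad * cos(lam), 0)
  chat <- c(sin(lam), -cos(lam), 0)
  uhat <- c(cos(lam), sin(lam), 0)
  vhat <- c(0, 0, 1)
  center <- src + g$sdd * chat
  corner <- center - (g$det_size[1] / 2) * uhat - (g$det_size[2] / 2) * vhat
  list(src = src, corner = corner, uhat = uhat, vhat = vhat,
       du = g$det_size[1] / g$det_pixels[1],
       dv = g$det_size[2] / g$det_pixels[2],
       nu = g$det_pixels[1], nv = g$det_pixels[2])
}

#' Ray through a detector pixel
#'
#' Returns the ray from the source position at `angle` through the center of
#' detector pixel `(u_index, v_index)` (0-based; pixel centers sit at
#' `(index + 0.5) * pitch`).
#'
#' @param geometry a [cone_beam_geometry].
#' @param angle gantry angle, degrees.
#' @param u_index,v_index 0-based pixel indices.
#' @return list with `origin` (source position, cm) and `direction`
#'   (unit vector).
#' @export
pixel_ray <- function(geometry, angle, u_index, v_index) {
  fr <- .det_frame(geometry, angle)
  if (u_index < 0 || u_index >= fr$nu || v_index < 0 || v_index >= fr$nv)
    stop("pixel index outside the detector grid")
  pt <- fr$corner + (u_index + 0.5) * fr$du * fr$uhat +
    (v_index + 0.5) * fr$dv * fr$vhat
  d <- pt - fr$src
  list(origin = fr$src, direction = d / sqrt(sum(d^2)))
}

#' Projection image
#'
#' A detector-plane raster for one projection angle. `component` labels what
#' the pixels hold: total signal `"R"`, primary `"P"`, scatter `"S"`, blank
#' `"B"`, air-normalized log `"r"`, or corrected log `"p"`. Intensity
#' components must be non-negative. `rel_uncertainty` is the fractional
#' 1-sigma statistical uncertainty per pixel, if known.
#'
#' @param pixels numeric matrix (u along rows, v along columns).
#' @param component one of `"R"`, `"P"`, `"S"`, `"B"`, `"r"`, `"p"`.
#' @param angle projection angle, degrees.
#' @param rel_uncertainty optional matrix of the same shape, `>= 0`.
#' @return object of class `projection_image`.
#' @export
projection_image <- function(pixels, component, angle,
                             rel_uncertainty = NULL) {
  component <- match.arg(component, c("R", "P", "S", "B", "r", "p"))
  stopifnot(is.matrix(pixels))
  if (component %in% c("R", "P", "S", "B") && any(pixels < 0))
    stop("intensity components must be non-negative")
  if (!is.null(rel_uncertainty)) {
    stopifnot(identical(dim(rel_uncertainty), dim(pixels)))
    if (any(rel_uncertainty < 0)) stop("rel_uncertainty must be >= 0")
  }
  structure(list(pixels = pixels, component = component, angle = angle,
                 rel_uncertainty = rel_uncertainty),
            class = "projection_image")
}

#' Projection set
#'
#' A collection of [projection_image]s sharing one geometry, keyed by
#' `(component, angle index)`.
#'
#' @param geometry a [cone_beam_geometry].
#' @param images list of [projection_image]s.
#' @return object of class `projection_set`.
#' @export
projection_set <- function(geometry, images) {
  stopifnot(inherits(geometry, "cone_beam_geometry"))
  ang <- arc_angles(geometry)
  for (im in images) {
    stopifnot(inherits(im, "projection_image"))
    if (!any(abs(ang - im$angle) < 1e-9))
      stop("image angle ", im$angle, " not in the geometry's schedule")
    if (!identical(dim(im$pixels), dim(images[[1]]$pixels)))
      stop("all images must share detector dimensions")
  }
  structure(list(geometry = geometry, images = images),
            class = "projection_set")
}

#' Fetch one image from a projection set
#'
#' @param ps a [projection_set].
#' @param component component label.
#' @param angle angle in degrees.
#' @return the matching [projection_image], or error.
#' @export
ps_get <- function(ps, component, angle) {
  for (im in ps$images)
    if (im$component == component && abs(im$angle - angle) < 1e-9) return(im)
  stop("no image with component ", component, " at angle ", angle)
}
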