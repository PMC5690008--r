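#' Write a voxel phantom in egsphant-style text layout
#'
#' Plain-text layout: number of materials, material names, grid dimensions,
#' the three voxel-boundary lists, the material-index block (one slice row
#' per line, digits/letters indexing the material list), and the density
#' block.
#'
#' @param phantom a [voxel_phantom].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_egsphant <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  d <- dim(phantom$density)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(phantom$materials)), con)
  writeLines(phantom$materials, con)
  writeLines(paste(d, collapse = " "), con)
  for (a in 1:3) {
    b <- phantom$origin[a] + (0:d[a]) * phantom$voxel_size[a]
    writeLines(paste(format(b, trim = TRUE, digits = 8), collapse = " "), con)
  }
  code <- c(as.character(1:9), LETTERS)
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2]))
      writeLines(paste(code[phantom$material_index[, j, k]], collapse = ""),
                 con)
    writeLines("", con)
  }
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2]))
      writeLines(paste(format(phantom$density[, j, k], trim = TRUE,
                              digits = 7), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read an egsphant-style text phantom
#'
#' @param path file written by [write_egsphant()].
#' @return a [voxel_phantom].
#' @export
read_egsphant <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path)
  nmat <- as.integer(ln[1])
  mats <- ln[1 + seq_len(nmat)]
  pos <- 2 + nmat
  d <- as.integer(strsplit(trimws(ln[pos]), "\\s+")[[1]])
  bounds <- list()
  for (a in 1:3) {
    bounds[[a]] <- as.numeric(strsplit(trimws(ln[pos + a]), "\\s+")[[1]])
    if (length(bounds[[a]]) != d[a] + 1) stop("corrupt boundary list")
  }
  pos <- pos + 4
  code <- c(as.character(1:9), LETTERS)
  idx <- array(0L, dim = d)
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      row <- strsplit(ln[pos], "")[[1]]
      idx[, j, k] <- match(row, code)
      pos <- pos + 1
    }
    pos <- pos + 1
  }
  dens <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      dens[, j, k] <- as.numeric(strsplit(trimws(ln[pos]), "\\s+")[[1]])
      pos <- pos + 1
    }
    pos <- pos + 1
  }
  vox <- vapply(bounds, function(b) b[2] - b[1], numeric(1))
  origin <- vapply(bounds, function(b) b[1], numeric(1))
  voxel_phantom(idx, dens, vox, origin, mats)
}

#' Write / read a volume in MetaImage (.mha) format
#'
#' Local single-file MetaImage: ASCII header followed by raw
#' double-precision voxel data (native endianness). Round trips are
#' bit-identical, including spacing, origin and the HU scale (stored as a
#' private `HUScale` header field).
#'
#' @param volume a [recon_volume].
#' @param path output path (`.mha`).
#' @return `path`, invisibly.
#' @export
write_metaimage <- function(volume, path) {
  stopifnot(inherits(volume, "recon_volume"))
  d <- dim(volume$mu)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           sprintf("BinaryDataByteOrderMSB = %s",
                   if (.Platform$endian == "big") "True" else "False"),
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g",
                   volume$voxel_size[1], volume$voxel_size[2],
                   volume$voxel_size[3]),
           sprintf("Offset = %.17g %.17g %.17g", volume$origin[1],
                   volume$origin[2], volume$origin[3]),
           sprintf("HUScale = %.17g", volume$hu_scale),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  writLines <- paste0(paste(hdr, collapse = "\n"), "\n")
  writeChar(writLines, con, eos = NULL)
  writeBin(as.numeric(volume$mu), con, size = 8)
  invisible(path)
}

#' @rdname write_metaimage
#' @export
read_metaimage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("corrupt header: no data section")
      if (ch == "\n") break
      line <- paste0(line, ch)
    }
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(hdr$ElementType, "MET_DOUBLE"))
    stop("unsupported element type: ", hdr$ElementType)
  d <- as.integer(strsplit(hdr$DimSize, " ")[[1]])
  vox <- as.numeric(strsplit(hdr$ElementSpacing, " ")[[1]])
  org <- as.numeric(strsplit(hdr$Offset, " ")[[1]])
  hu <- as.numeric(hdr$HUScale)
  v <- readBin(con, "numeric", n = prod(d), size = 8)
  dim(v) <- d
  recon_volume(v, vox, org, hu)
}

#' Write / read a run configuration as JSON
#'
#' Serializes the reproducibility-relevant part of a correction
#' configuration — geometry, spectrum, correction and variance-reduction
#' parameters, grids and seed — with explicit units in the key names.
#' Reading validates the field set and rebuilds the typed objects; unknown
#' keys are rejected.
#'
#' @param config list from [correction_config()].
#' @param path JSON file path.
#' @return `path` (write) / a configuration list (read), invisibly.
#' @export
write_run_config <- function(config, path) {
  g <- config$geometry
  obj <- list(
    geometry = list(sad_cm = g$sad, sdd_cm = g$sdd,
                    det_size_cm = g$det_size, det_pixels = g$det_pixels,
                    arc_start_deg = g$arc_start,
                    arc_extent_deg = g$arc_extent,
                    n_projections = g$n_projections),
    spectrum = list(mode = config$spectrum$mode,
                    energy_kev = config$spectrum$lines$energy,
                    weight = config$spectrum$lines$weight),
    correction = list(alpha = config$params$alpha,
                      beta = config$params$beta,
                      max_iter = config$params$max_iter,
                      conv_tol = config$params$conv_tol),
    vrt = list(n_split = config$vrt$n_split,
               rr_factor = config$vrt$rr_factor,
               path_stretch = config$vrt$path_stretch,
               photon_cutoff_kev = config$vrt$photon_cutoff),
    n_histories = config$n_histories,
    scoring_pixels = config$scoring_geometry$det_pixels,
    recon_dims = config$recon_grid$dims,
    recon_voxel_cm = config$recon_grid$voxel_size,
    seed = config$seed,
    replicate_projections = isTRUE(config$replicate_projections))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @param ramp a [material_ramp] to attach to the rebuilt configuration.
#' @export
read_run_config <- function(path, ramp = default_catphan_ramp()) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("geometry", "spectrum", "correction", "vrt", "n_histories",
             "scoring_pixels", "recon_dims", "recon_voxel_cm", "seed",
             "replicate_projections")
  extra <- setdiff(names(obj), known)
  if (length(extra) > 0)
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  g <- obj$geometry
  geom <- cone_beam_geometry(g$sad_cm, g$sdd_cm, g$det_size_cm,
                             g$det_pixels, g$arc_start_deg,
                             g$arc_extent_deg, g$n_projections)
  spec <- structure(list(lines = data.frame(energy = obj$spectrum$energy_kev,
                                            weight = obj$spectrum$weight),
                         mode = obj$spectrum$mode),
                    class = "xray_spectrum")
  params <- correction_params(obj$correction$alpha, obj$correction$beta,
                              obj$correction$max_iter,
                              obj$correction$conv_tol)
  vrt <- vrt_params(obj$vrt$n_split, obj$vrt$rr_factor,
                    obj$vrt$path_stretch,
                    photon_cutoff = obj$vrt$photon_cutoff_kev)
  correction_config(geom, spec, params, ramp, vrt = vrt,
                    n_histories = obj$n_histories,
                    recon_grid = list(dims = obj$recon_dims,
                                      voxel_size = obj$recon_voxel_cm),
                    scoring_pixels = obj$scoring_pixels, seed = obj$seed,
                    replicate_projections = obj$replicate_projections)
}

#' Published Catphan-600 ROI statistics
#'
#' The per-material ROI mean CT number, standard deviation, CT-number
#' difference to the planning CT, and CNR, for the planning CT (`pCT`), the
#' uncorrected CBCT (`raw`), the scatter-corrected CBCT (`corrected`), and
#' the vendor default reconstruction (`varian`), on the water-is-1024-HU
#' scale. These printed values are inputs for metric arithmetic (e.g.
#' [metrics_report_from_stats()]); they cannot be recomputed without the
#' physical phantom and scanner.
#'
#' @return data.frame with columns `material`, `recon`, `mean`, `sd`,
#'   `dhu`, `cnr`.
#' @export
catphan_roi_table <- function() {
  f <- system.file("extdata", "catphan_roi_stats.csv",
                   package = "cbctscatter")
  utils::read.csv(f)
}
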