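## File surface: multi-page TIFF stacks with a JSON metadata sidecar
## (<file>.json), YAML optical configs, two-column CSV spectra.
## The TIFF pages store z-slices normalized to [0, 1] as 32-bit samples;
## the sidecar records the scale factor, voxel sizes, channel name and bit
## depth exactly.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read an image stack as multi-page TIFF
#'
#' Voxel sizes, channel name, bit depth and the normalization scale are kept
#' in a JSON sidecar next to the TIFF and restored exactly on read.
#'
#' @param image An [image_stack()] (or a [new_psf()] for `write_psf()`).
#' @param path Output TIFF path.
#' @return `write_stack()` the path invisibly; `read_stack()` an
#'   [image_stack()].
#' @export
write_stack <- function(image, path) {
  stopifnot(inherits(image, "image_stack"))
  x <- image$data
  scale <- max(x, 1e-300)
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(kind = "image_stack", dim = dim(x), voxel = image$voxel,
               channel = image$channel, scale = scale,
               bit_depth = image$meta$bit_depth %||% 32L,
               meta = image$meta)
  writeLines(as.character(jsonlite::toJSON(meta, digits = NA,
                                           auto_unbox = TRUE, null = "null")),
             sidecar_path(path))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(paste(readLines(sidecar_path(path)),
                                   collapse = "\n"))
  d <- as.integer(meta$dim)
  x <- array(0, dim = d)
  for (k in seq_len(d[3])) x[, , k] <- pages[[k]] * meta$scale
  image_stack(x, voxel = as.numeric(meta$voxel), channel = meta$channel,
              meta = c(meta$meta, list(bit_depth = meta$bit_depth)))
}

#' Write / read a PSF as multi-page TIFF with metadata sidecar
#'
#' @param psf A [new_psf()].
#' @param path Output TIFF path.
#' @return `write_psf()` the path invisibly; `read_psf()` a [new_psf()].
#' @export
write_psf <- function(psf, path) {
  stopifnot(inherits(psf, "psf"))
  x <- psf$values
  scale <- max(x)
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(kind = "psf", dim = dim(x),
               voxel = c(psf$dx, psf$dy, psf$dz), scale = scale,
               meta = psf$meta)
  writeLines(as.character(jsonlite::toJSON(meta, digits = NA,
                                           auto_unbox = TRUE, null = "null")),
             sidecar_path(path))
  invisible(path)
}

#' @rdname write_psf
#' @export
read_psf <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(paste(readLines(sidecar_path(path)),
                                   collapse = "\n"))
  d <- as.integer(meta$dim)
  x <- array(0, dim = d)
  for (k in seq_len(d[3])) x[, , k] <- pages[[k]] * meta$scale
  vox <- as.numeric(meta$voxel)
  new_psf(x, vox[1], vox[2], vox[3], meta = as.list(meta$meta))
}

#' Write / read an optical configuration as YAML
#'
#' Keys match the [optical_config()] field names.
#'
#' @param config An [optical_config()].
#' @param path YAML file path.
#' @return `write_optical_config()` the path invisibly;
#'   `read_optical_config()` an [optical_config()].
#' @export
write_optical_config <- function(config, path) {
  stopifnot(inherits(config, "optical_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_optical_config
#' @export
read_optical_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(optical_config, v[c("na", "immersion_index", "lambda_exc",
                              "lambda_em", "photon_order", "pinhole_au",
                              "dx", "dy", "dz")])
}

#' Write / read a spectrum as two-column CSV
#'
#' Columns `wavelength` (nm) and `intensity`.
#'
#' @param spectrum A [qd_spectrum()].
#' @param path CSV file path.
#' @return `write_spectrum()` the path invisibly; `read_spectrum()` a
#'   [qd_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "qd_spectrum"))
  utils::write.csv(data.frame(wavelength = spectrum$wavelengths,
                              intensity = spectrum$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  qd_spectrum(df$wavelength, df$intensity)
}

#' Write a phantom to disk
#'
#' One TIFF per label (`<stem>_<label>.tif` + sidecars) and the exact
#' geometry as `<stem>_geometry.json`.
#'
#' @param ph A [phantom()].
#' @param stem Path stem (no extension).
#' @return Invisibly, the written file paths.
#' @export
write_phantom <- function(ph, stem) {
  stopifnot(inherits(ph, "phantom"))
  paths <- character(0)
  for (lab in names(ph$density)) {
    p <- sprintf("%s_%s.tif", stem, lab)
    write_stack(image_stack(ph$density[[lab]], ph$voxel, channel = lab), p)
    paths <- c(paths, p)
  }
  gp <- sprintf("%s_geometry.json", stem)
  writeLines(geometry_to_json(ph), gp)
  invisible(c(paths, gp))
}
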