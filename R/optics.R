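#' Optical configuration for one confocal channel
#'
#' Bundles the optical parameters that determine a channel's point spread
#' function: objective numerical aperture and immersion index, excitation and
#' emission wavelengths, the photon order of the exciton process (1 = mono-,
#' 2 = bi-, 3 = tri-exciton), the confocal pinhole diameter in Airy units,
#' and the voxel sizes of the sampling grid.
#'
#' @param na Numerical aperture of the objective (dimensionless).
#' @param immersion_index Refractive index of the immersion medium.
#' @param lambda_exc Excitation wavelength in nm.
#' @param lambda_em Emission wavelength in nm, or `NA` to let PSF builders
#'   pick the default for the photon order (655/620/580 nm).
#' @param photon_order Integer exciton order (>= 1).
#' @param pinhole_au Pinhole diameter in Airy units (1 AU = 1.22 lambda/NA).
#' @param dx,dy,dz Voxel sizes in nm.
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(lambda_exc = 405, lambda_em = 655)
#' @export
optical_config <- function(na = 1.4, immersion_index = 1.515,
                           lambda_exc = 405, lambda_em = 655,
                           photon_order = 1L, pinhole_au = 0.7,
                           dx = 50, dy = dx, dz = 150) {
  if (!is.numeric(na) || na <= 0 || na >= immersion_index)
    stop("`na` must satisfy 0 < na < immersion_index", call. = FALSE)
  for (lam in c(lambda_exc, if (!is.na(lambda_em)) lambda_em)) {
    if (lam < 300 || lam > 800)
      stop("wavelengths must lie in [300, 800] nm", call. = FALSE)
  }
  photon_order <- as.integer(photon_order)
  if (photon_order < 1L) stop("`photon_order` must be >= 1", call. = FALSE)
  if (pinhole_au <= 0) stop("`pinhole_au` must be positive", call. = FALSE)
  if (any(c(dx, dy, dz) <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  structure(
    list(na = na, immersion_index = immersion_index,
         lambda_exc = lambda_exc, lambda_em = lambda_em,
         photon_order = photon_order, pinhole_au = pinhole_au,
         dx = dx, dy = dy, dz = dz),
    class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("<optical_config> NA %.2f (n = %.3f), ex %g nm / em %s nm,\n",
              x$na, x$immersion_index, x$lambda_exc,
              ifelse(is.na(x$lambda_em), "auto", format(x$lambda_em))))
  cat(sprintf("  photon order %d, pinhole %.2f AU, voxel %g x %g x %g nm\n",
              x$photon_order, x$pinhole_au, x$dx, x$dy, x$dz))
  invisible(x)
}

#' Airy unit diameter
#'
#' One Airy unit is the diameter of the Airy disk, `1.22 * lambda_em / NA`.
#' Confocal pinhole diameters are conventionally quoted in this unit.
#'
#' @param lambda_em Emission wavelength in nm.
#' @param na Numerical aperture.
#' @return Diameter of 1 AU in nm.
#' @examples
#' airy_unit_diameter(655, 1.4) # 570.8 nm
#' @export
airy_unit_diameter <- function(lambda_em, na) {
  if (!is.numeric(lambda_em) || !is.numeric(na) || lambda_em <= 0 || na <= 0)
    stop("`lambda_em` and `na` must be positive", call. = FALSE)
  1.22 * lambda_em / na
}

## Default emission wavelengths per exciton order used for PSF generation.
## Spectrally the tri-exciton band is centred at 590 nm; for PSF wavelengths
## the 3-photon case is taken at 580 nm (the centre of the detection band
## actually used for tri-exciton imaging).
psf_default_em <- c(655, 620, 580)

# ---- PSF container ----------------------------------------------------------

#' Construct a PSF object
#'
#' A PSF is a normalized non-negative 3D array with voxel sizes and the voxel
#' index of its maximum. Values are normalized to sum to one.
#'
#' @param values Non-negative 3D array.
#' @param dx,dy,dz Voxel sizes in nm.
#' @param meta Optional list of provenance metadata (model, wavelengths, ...).
#' @return Object of class `psf` with elements `values`, `dx`, `dy`, `dz`,
#'   `center` (1-based voxel index of the maximum) and `meta`.
#' @export
new_psf <- function(values, dx, dy, dz, meta = list()) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array", call. = FALSE)
  if (any(values < 0)) stop("PSF values must be non-negative", call. = FALSE)
  s <- sum(values)
  if (s <= 0) stop("PSF has zero total intensity", call. = FALSE)
  values <- values / s
  ctr <- which(values == max(values), arr.ind = TRUE)[1, ]
  structure(list(values = values, dx = dx, dy = dy, dz = dz,
                 center = as.integer(ctr), meta = meta),
            class = "psf")
}

#' @export
print.psf <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<psf> %d x %d x %d voxels @ %g x %g x %g nm (%s)\n",
              d[1], d[2], d[3], x$dx, x$dy, x$dz,
              if (length(x$meta)) paste(unlist(x$meta), collapse = ", ") else "?"))
  invisible(x)
}

check_odd_shape <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L) || any(shape %% 2L == 0L))
    stop("`shape` must be three odd positive integers so a center voxel exists",
         call. = FALSE)
  shape
}

## Centered physical coordinates (nm) along one axis of an odd-length grid.
axis_coords <- function(n, d) (seq_len(n) - (n %/% 2L + 1L)) * d

# ---- PSF models -------------------------------------------------------------

## 3D Gaussian intensity distribution from lateral/axial FWHMs.
gaussian_psf_values <- function(shape, dx, dy, dz, fwhm_lat, fwhm_ax) {
  sl <- fwhm_lat / (2 * sqrt(2 * log(2)))
  sa <- fwhm_ax / (2 * sqrt(2 * log(2)))
  gx <- exp(-axis_coords(shape[1], dx)^2 / (2 * sl^2))
  gy <- exp(-axis_coords(shape[2], dy)^2 / (2 * sl^2))
  gz <- exp(-axis_coords(shape[3], dz)^2 / (2 * sa^2))
  outer(outer(gx, gy), gz)
}

## Paraxial scalar (Born-Wolf/Debye) focal intensity on the voxel grid.
## h(r, z) = int_0^1 J0(k NA r rho) exp(-i k NA^2 z rho^2 / (2 n)) rho drho
## evaluated by Simpson quadrature over the pupil radius.
scalar_psf_values <- function(shape, dx, dy, dz, lambda, na, n_imm,
                              n_quad = 101L) {
  k <- 2 * pi / lambda
  rho <- seq(0, 1, length.out = n_quad)
  w <- rep(c(4, 2), length.out = n_quad - 2L)
  w <- c(1, w, 1) * (rho[2] - rho[1]) / 3  # Simpson weights
  xs <- axis_coords(shape[1], dx); ys <- axis_coords(shape[2], dy)
  zs <- axis_coords(shape[3], dz)
  r <- sqrt(outer(xs^2, ys^2, `+`))
  ru <- sort(unique(as.vector(r)))
  ## J0 part is shared by all z-planes
  J <- besselJ(k * na * outer(rho, ru), 0)          # n_quad x n_r
  vals <- array(0, dim = shape)
  for (iz in seq_along(zs)) {
    phase <- exp(-1i * k * na^2 * zs[iz] * rho^2 / (2 * n_imm))
    amp <- colSums((w * rho * phase) * J)           # over rho
    inten <- Mod(amp)^2
    vals[, , iz] <- matrix(inten[match(r, ru)], nrow = shape[1])
  }
  vals
}

## Gaussian-model lateral / axial FWHM (nm) of a single-photon focus.
gaussian_fwhms <- function(lambda, na, n_imm) {
  c(lat = 0.51 * lambda / na,
    ax = 0.88 * lambda / (n_imm - sqrt(n_imm^2 - na^2)))
}

#' Single-photon excitation PSF
#'
#' Intensity distribution of the focused excitation light at `lambda_exc`.
#' The `gaussian` model uses lateral FWHM `0.51 lambda/NA` and axial FWHM
#' `0.88 lambda / (n - sqrt(n^2 - NA^2))`; the `scalar_diffraction` model
#' evaluates the paraxial scalar Debye integral.
#'
#' @param config An [optical_config()].
#' @param mode `"gaussian"` or `"scalar_diffraction"`.
#' @param shape Odd voxel dimensions of the PSF grid.
#' @return A [new_psf()] object.
#' @export
make_excitation_psf <- function(config, mode = c("gaussian", "scalar_diffraction"),
                                shape = c(33, 33, 33)) {
  mode <- match.arg(mode)
  shape <- check_odd_shape(shape)
  if (config$na >= config$immersion_index)
    stop("NA must be below the immersion index", call. = FALSE)
  vals <- switch(mode,
    gaussian = {
      fw <- gaussian_fwhms(config$lambda_exc, config$na, config$immersion_index)
      gaussian_psf_values(shape, config$dx, config$dy, config$dz,
                          fw["lat"], fw["ax"])
    },
    scalar_diffraction = scalar_psf_values(shape, config$dx, config$dy,
                                           config$dz, config$lambda_exc,
                                           config$na, config$immersion_index))
  new_psf(vals, config$dx, config$dy, config$dz,
          meta = list(kind = "excitation", model = mode,
                      lambda = config$lambda_exc))
}

## Anti-aliased uniform disk kernel (2D matrix) of given radius in nm.
disk_kernel <- function(nx, ny, dx, dy, radius) {
  r <- sqrt(outer(axis_coords(nx, dx)^2, axis_coords(ny, dy)^2, `+`))
  h <- min(dx, dy)
  k <- pmin(pmax((radius - r) / h + 0.5, 0), 1)
  if (sum(k) == 0) k[nx %/% 2L + 1L, ny %/% 2L + 1L] <- 1
  k / sum(k)
}

## Circular 2D convolution of a matrix with a centered kernel of equal size.
conv2_circ <- function(mat, kern) {
  n <- dim(mat)
  ## shift kernel center to index (1,1)
  cx <- n[1] %/% 2L + 1L; cy <- n[2] %/% 2L + 1L
  kern <- kern[c(cx:n[1], seq_len(cx - 1L)), c(cy:n[2], seq_len(cy - 1L))]
  Re(fft(fft(mat) * fft(kern), inverse = TRUE)) / prod(n)
}

#' Confocal detection PSF
#'
#' Emission-wavelength PSF convolved laterally (slice by slice) with a uniform
#' disk whose diameter is the pinhole size in Airy units. No axial pinhole
#' effect is modeled beyond what the excitation-detection product provides.
#'
#' @inheritParams make_excitation_psf
#' @return A [new_psf()] object.
#' @export
make_detection_psf <- function(config, mode = c("gaussian", "scalar_diffraction"),
                               shape = c(33, 33, 33)) {
  mode <- match.arg(mode)
  shape <- check_odd_shape(shape)
  if (is.na(config$lambda_em))
    stop("`lambda_em` must be set for a detection PSF", call. = FALSE)
  if (config$pinhole_au <= 0) stop("`pinhole_au` must be positive", call. = FALSE)
  vals <- switch(mode,
    gaussian = {
      fw <- gaussian_fwhms(config$lambda_em, config$na, config$immersion_index)
      gaussian_psf_values(shape, config$dx, config$dy, config$dz,
                          fw["lat"], fw["ax"])
    },
    scalar_diffraction = scalar_psf_values(shape, config$dx, config$dy,
                                           config$dz, config$lambda_em,
                                           config$na, config$immersion_index))
  radius <- config$pinhole_au * airy_unit_diameter(config$lambda_em, config$na) / 2
  kern <- disk_kernel(shape[1], shape[2], config$dx, config$dy, radius)
  for (iz in seq_len(shape[3]))
    vals[, , iz] <- pmax(conv2_circ(vals[, , iz], kern), 0)
  new_psf(vals, config$dx, config$dy, config$dz,
          meta = list(kind = "detection", model = mode,
                      lambda = config$lambda_em, pinhole_au = config$pinhole_au))
}

#' n-exciton confocal PSF
#'
#' Effective PSF of mono-/bi-/tri-exciton confocal imaging: the excitation
#' intensity PSF raised to the photon order (exciton generation scales with
#' the n-th power of the excitation intensity) times the detection PSF at the
#' order's emission wavelength. Defaults: 655 nm (order 1), 620 nm (order 2),
#' 580 nm (order 3) when the config leaves `lambda_em` as `NA`.
#'
#' @inheritParams make_excitation_psf
#' @param em_defaults Emission wavelengths used per order when the config has
#'   `lambda_em = NA`.
#' @return A [new_psf()] object.
#' @export
make_nexciton_psf <- function(config, mode = c("gaussian", "scalar_diffraction"),
                              shape = c(33, 33, 33),
                              em_defaults = psf_default_em) {
  mode <- match.arg(mode)
  n <- config$photon_order
  if (!n %in% 1:3)
    stop("unsupported photon order: must be 1, 2 or 3", call. = FALSE)
  exc <- make_excitation_psf(config, mode, shape)
  det_cfg <- config
  if (is.na(det_cfg$lambda_em)) det_cfg$lambda_em <- em_defaults[n]
  det <- make_detection_psf(det_cfg, mode, shape)
  new_psf(exc$values^n * det$values, config$dx, config$dy, config$dz,
          meta = list(kind = "nexciton", model = mode, order = n,
                      lambda_exc = config$lambda_exc,
                      lambda_em = det_cfg$lambda_em,
                      pinhole_au = config$pinhole_au))
}

## Linear-interpolated FWHM of a sampled single-peak profile.
## Errors if the peak touches the boundary or fewer than 5 samples exist.
profile_fwhm <- function(positions, values, baseline = 0) {
  n <- length(values)
  if (n < 5L) stop("profile needs at least 5 samples", call. = FALSE)
  ip <- which.max(values)
  if (ip == 1L || ip == n)
    stop("peak on profile boundary: FWHM unmeasurable", call. = FALSE)
  half <- baseline + (values[ip] - baseline) / 2
  left <- which(values[seq_len(ip)] < half)
  right <- which(values[ip:n] < half) + ip - 1L
  if (length(left) == 0L || length(right) == 0L)
    stop("profile does not fall below half maximum: FWHM unmeasurable",
         call. = FALSE)
  il <- max(left)
  ir <- min(right)
  xl <- positions[il] + (half - values[il]) /
    (values[il + 1L] - values[il]) * (positions[il + 1L] - positions[il])
  xr <- positions[ir - 1L] + (half - values[ir - 1L]) /
    (values[ir] - values[ir - 1L]) * (positions[ir] - positions[ir - 1L])
  xr - xl
}

#' FWHM of a PSF along one axis
#'
#' Full width at half maximum of the through-center profile, with linear
#' interpolation between samples at the half-maximum crossings.
#'
#' @param psf A [new_psf()] object.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return FWHM in nm.
#' @export
psf_fwhm <- function(psf, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  ctr <- psf$center
  v <- switch(axis,
              x = psf$values[, ctr[2], ctr[3]],
              y = psf$values[ctr[1], , ctr[3]],
              z = psf$values[ctr[1], ctr[2], ])
  d <- switch(axis, x = psf$dx, y = psf$dy, z = psf$dz)
  profile_fwhm(seq_along(v) * d, v)
}

#' Nyquist-compliant voxel spacing for a PSF
#'
#' Maximum admissible lateral and axial voxel sizes, taken as the PSF FWHM
#' divided by a sampling factor (default 2.3, the usual deconvolution
#' convention).
#'
#' @param psf A [new_psf()] object.
#' @param factor Sampling factor dividing the FWHM.
#' @return Named numeric `c(dx_max = , dz_max = )` in nm.
#' @export
nyquist_sampling <- function(psf, factor = 2.3) {
  lat <- mean(c(psf_fwhm(psf, "x"), psf_fwhm(psf, "y")))
  ax <- psf_fwhm(psf, "z")
  c(dx_max = lat / factor, dz_max = ax / factor)
}
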