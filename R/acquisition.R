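#' Detector model
#'
#' PMT-style detector: Poisson photon statistics at the quantum efficiency,
#' linear gain, constant offset, additive Gaussian read noise, and clipping
#' to the digitizer range.
#'
#' @param quantum_efficiency Photon detection efficiency in (0, 1].
#' @param gain Counts per detected photon.
#' @param offset Constant offset in counts.
#' @param read_noise_sd Read-noise standard deviation in counts.
#' @param bit_depth Digitizer depth in bits (12 for typical confocals).
#' @return Object of class `detector_model`.
#' @export
detector_model <- function(quantum_efficiency = 0.8, gain = 1, offset = 10,
                           read_noise_sd = 2, bit_depth = 12L) {
  if (quantum_efficiency <= 0 || quantum_efficiency > 1)
    stop("`quantum_efficiency` must be in (0, 1]", call. = FALSE)
  stopifnot(gain > 0, offset >= 0, read_noise_sd >= 0, bit_depth >= 1)
  structure(list(quantum_efficiency = quantum_efficiency, gain = gain,
                 offset = offset, read_noise_sd = read_noise_sd,
                 bit_depth = as.integer(bit_depth),
                 max_count = 2^bit_depth - 1),
            class = "detector_model")
}

#' Channel configuration
#'
#' One acquisition channel: the laser line and relative intensity, the
#' detection band, the optics, and the exciton photon order whose PSF forms
#' the image. Laser percentages map linearly to relative intensity units
#' (100% = 10 saturation units, so typical tri-exciton settings of 20-40%
#' sit at 2-4 units).
#'
#' @param name Channel / fluorophore name (must match a phantom label for
#'   the primary signal).
#' @param excitation_wavelength Laser line, nm.
#' @param laser_intensity Relative excitation intensity (saturation units).
#' @param emission_band A [band()].
#' @param optical An [optical_config()]; its `photon_order` and wavelengths
#'   drive PSF generation.
#' @return Object of class `channel_config`.
#' @export
channel_config <- function(name = "QD655", excitation_wavelength = 405,
                           laser_intensity = 1,
                           emission_band = band(635, 675),
                           optical = optical_config(
                             lambda_exc = excitation_wavelength,
                             lambda_em = NA, photon_order = 1L)) {
  if (laser_intensity < 0) stop("`laser_intensity` must be >= 0", call. = FALSE)
  stopifnot(inherits(emission_band, "band"), inherits(optical, "optical_config"))
  structure(list(name = name,
                 excitation_wavelength = excitation_wavelength,
                 laser_intensity = laser_intensity,
                 emission_band = emission_band, optical = optical),
            class = "channel_config")
}

#' Convenience channels for conventional QD and tri-exciton imaging
#'
#' `channel_qd()`: order-1 imaging at 405 nm excitation, 635-675 nm
#' detection, low laser power. `channel_qdtx()`: order-3 tri-exciton imaging
#' at 405 nm excitation, 580-610 nm detection, high laser power.
#'
#' @param laser_pct Laser power as percent of maximum (linear map to
#'   relative units, 100% = 10).
#' @param excitation_wavelength Laser line, nm.
#' @param dx,dy,dz Voxel sizes (nm) for the PSF grid.
#' @return A [channel_config()].
#' @export
channel_qd <- function(laser_pct = 2, excitation_wavelength = 405,
                       dx = 50, dy = dx, dz = 150) {
  channel_config("QD655", excitation_wavelength,
                 laser_intensity = laser_pct / 10,
                 emission_band = band(635, 675),
                 optical = optical_config(lambda_exc = excitation_wavelength,
                                          lambda_em = NA, photon_order = 1L,
                                          dx = dx, dy = dy, dz = dz))
}

#' @rdname channel_qd
#' @export
channel_qdtx <- function(laser_pct = 30, excitation_wavelength = 405,
                         dx = 50, dy = dx, dz = 150) {
  channel_config("QD655", excitation_wavelength,
                 laser_intensity = laser_pct / 10,
                 emission_band = band(580, 610),
                 optical = optical_config(lambda_exc = excitation_wavelength,
                                          lambda_em = NA, photon_order = 3L,
                                          dx = dx, dy = dy, dz = dz))
}

# ---- image containers -------------------------------------------------------

#' Image stack
#'
#' A 3D voxel array with physical voxel sizes and channel metadata.
#'
#' @param data 3D numeric array (counts).
#' @param voxel Voxel sizes `c(dx, dy, dz)` in nm.
#' @param channel Channel name.
#' @param meta Free-form metadata list (seed, PSF model, detector, ...).
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(data, voxel, channel = "", meta = list()) {
  stopifnot(length(dim(data)) == 3L, length(voxel) == 3L, all(voxel > 0))
  structure(list(data = data, voxel = as.numeric(voxel),
                 channel = channel, meta = meta),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> '%s' %d x %d x %d voxels @ %g x %g x %g nm, range [%.3g, %.3g]\n",
              x$channel, d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3],
              min(x$data), max(x$data)))
  invisible(x)
}

# ---- FFT convolution --------------------------------------------------------

## embed a (smaller, odd-shaped) kernel into an array of dims `n`, centered
## at index (1,1,1) with wrap-around, and return its FFT
kernel_fft <- function(kern, n) {
  kd <- dim(kern)
  if (any(kd > n)) stop("PSF larger than image: crop the PSF", call. = FALSE)
  big <- array(0, dim = n)
  idx <- lapply(1:3, function(a) {
    off <- seq_len(kd[a]) - (kd[a] %/% 2L + 1L)
    ((off %% n[a]) + 1L)
  })
  big[idx[[1]], idx[[2]], idx[[3]]] <- kern
  fft(big)
}

## circular convolution with a centered kernel (any smaller odd shape)
conv3_circ <- function(x, kern) {
  n <- dim(x)
  Re(fft(fft(x) * kernel_fft(kern, n), inverse = TRUE)) / prod(n)
}

## reflective padding along all axes
pad_reflect <- function(x, pad) {
  n <- dim(x)
  idx <- lapply(1:3, function(a) {
    p <- pad[a]
    if (p == 0) return(seq_len(n[a]))
    if (n[a] == 1L) return(rep(1L, n[a] + 2L * p))
    pre <- pmin(pmax(seq.int(p + 1L, 2L), 1L), n[a])
    post <- pmin(pmax(seq.int(n[a] - 1L, n[a] - p), 1L), n[a])
    c(pre, seq_len(n[a]), post)
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Convolve a volume with a PSF (reflective-boundary FFT convolution)
#'
#' @param x 3D array.
#' @param psf A [new_psf()] or 3D kernel array (odd dims, centered).
#' @return Convolved 3D array of the same dimensions.
#' @export
fft_convolve <- function(x, psf) {
  kern <- if (inherits(psf, "psf")) psf$values else psf
  kd <- dim(kern)
  pad <- pmin(kd %/% 2L, dim(x))
  xp <- pad_reflect(x, pad)
  out <- conv3_circ(xp, kern)
  n <- dim(x)
  out[pad[1] + seq_len(n[1]), pad[2] + seq_len(n[2]), pad[3] + seq_len(n[3]),
      drop = FALSE]
}

## pick an odd PSF shape covering ~3 FWHM per axis, capped below image dims
auto_psf_shape <- function(config, dim, em_defaults = psf_default_em) {
  lam_em <- if (is.na(config$lambda_em))
    em_defaults[min(config$photon_order, 3L)] else config$lambda_em
  fw_ex <- gaussian_fwhms(config$lambda_exc, config$na, config$immersion_index)
  fw_em <- gaussian_fwhms(lam_em, config$na, config$immersion_index)
  pin <- config$pinhole_au * airy_unit_diameter(lam_em, config$na)
  lat <- 3 * (fw_em["lat"] + pin)
  ax <- 3 * (fw_ex["ax"] + fw_em["ax"])
  want <- c(lat / config$dx, lat / config$dy, ax / config$dz)
  shape <- pmax(9L, as.integer(ceiling(want)))
  shape <- shape + (1L - shape %% 2L)            # make odd
  cap <- pmax(3L, dim - (1L - dim %% 2L))        # odd cap <= image dims
  pmin(shape, cap)
}

# ---- expected-signal model --------------------------------------------------

## Absolute band signal (photons per emitter) of one fluorophore label in a
## channel: excitation efficiency at the laser line enters the saturating
## power law via the effective intensity; the emission spectrum at that
## intensity is integrated over the detection band.
label_band_signal <- function(fluor, channel,
                              wavelengths = seq(380, 780, by = 1)) {
  i_eff <- channel$laser_intensity *
    excitation_efficiency(fluor, channel$excitation_wavelength)
  sp <- emission_spectrum(fluor, i_eff, wavelengths)
  band_integrate(sp, channel$emission_band, absolute = TRUE)
}

#' Render one confocal channel of a phantom
#'
#' Image formation: for every phantom label, emitter density times that
#' label's absolute band signal (excitation efficiency at the laser line,
#' saturating exciton power law, emission-spectrum integral over the
#' detection band), summed and convolved with the channel's n-exciton PSF;
#' then Poisson photon noise, gain, offset, Gaussian read noise and clipping.
#' Bleed-through of off-target labels is emergent from their excitation and
#' emission spectra.
#'
#' @param ph A [phantom()].
#' @param channel A [channel_config()].
#' @param detector A [detector_model()].
#' @param seed RNG seed for the noise draws (ignored when `noise = FALSE`).
#' @param noise Apply Poisson/read noise; `FALSE` returns the noiseless
#'   expectation `photons * QE * gain + offset`.
#' @param panel Fluorophore models, named by phantom label.
#' @param psf Optional precomputed [new_psf()] on the phantom grid;
#'   otherwise built from `channel$optical` (`psf_mode` model).
#' @param psf_mode PSF model when `psf` is not supplied.
#' @return An [image_stack()] of detector counts.
#' @export
render_channel <- function(ph, channel, detector = detector_model(),
                           seed = NULL, noise = TRUE,
                           panel = fluorophore_panel(), psf = NULL,
                           psf_mode = "gaussian") {
  stopifnot(inherits(ph, "phantom"), inherits(channel, "channel_config"))
  if (is.null(psf)) {
    cfg <- channel$optical
    cfg$dx <- ph$voxel[1]; cfg$dy <- ph$voxel[2]; cfg$dz <- ph$voxel[3]
    psf <- make_nexciton_psf(cfg, psf_mode, auto_psf_shape(cfg, ph$dim))
  }
  if (max(abs(c(psf$dx, psf$dy, psf$dz) - ph$voxel)) > 1e-6)
    stop("PSF and phantom voxel sizes differ: resample required", call. = FALSE)
  expected <- array(0, dim = ph$dim)
  any_signal <- FALSE
  for (lab in names(ph$density)) {
    if (all(ph$density[[lab]] == 0)) next
    fluor <- panel[[lab]]
    if (is.null(fluor))
      stop(sprintf("no fluorophore model for label '%s'", lab), call. = FALSE)
    sig <- label_band_signal(fluor, channel)
    if (sig > 0) any_signal <- TRUE
    expected <- expected + ph$density[[lab]] * sig
  }
  if (!any_signal && any(vapply(ph$density, function(d) any(d > 0), TRUE)))
    warning("no emission falls into the detection band: zero signal",
            call. = FALSE)
  photons <- fft_convolve(expected, psf)
  photons[photons < 0] <- 0
  counts <- apply_detector(photons, detector, seed, noise)
  image_stack(counts, ph$voxel, channel = channel$name,
              meta = list(excitation = channel$excitation_wavelength,
                          band = c(channel$emission_band$low,
                                   channel$emission_band$high),
                          photon_order = channel$optical$photon_order,
                          psf_model = psf$meta$model %||% "supplied",
                          seed = seed, noise = noise))
}

apply_detector <- function(photons, detector, seed, noise) {
  if (!noise)
    return(array(pmin(photons * detector$quantum_efficiency * detector$gain +
                        detector$offset, detector$max_count),
                 dim = dim(photons)))
  if (!is.null(seed)) set.seed(seed)
  n <- length(photons)
  counts <- stats::rpois(n, photons * detector$quantum_efficiency) *
    detector$gain + detector$offset
  if (detector$read_noise_sd > 0)
    counts <- counts + stats::rnorm(n, 0, detector$read_noise_sd)
  array(pmin(pmax(counts, 0), detector$max_count), dim = dim(photons))
}

# ---- spectral scan ----------------------------------------------------------

#' Spectral stack
#'
#' Per-band images from a spectral emission scan.
#'
#' @param data 4D array `[x, y, z, band]`.
#' @param band_centers Band center wavelengths, nm.
#' @param bandwidth Band width, nm.
#' @param voxel Voxel sizes, nm.
#' @param meta Metadata list.
#' @return Object of class `spectral_stack`.
#' @export
spectral_stack <- function(data, band_centers, bandwidth, voxel,
                           meta = list()) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] == length(band_centers))
  structure(list(data = data, band_centers = band_centers,
                 bandwidth = bandwidth, voxel = as.numeric(voxel),
                 meta = meta),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_stack> %d bands of %g nm (%g-%g nm), %d x %d x %d voxels\n",
              d[4], x$bandwidth, min(x$band_centers) - x$bandwidth / 2,
              max(x$band_centers) + x$bandwidth / 2, d[1], d[2], d[3]))
  invisible(x)
}

#' Simulate a spectral emission scan
#'
#' Renders one image per contiguous detection band across `range`. All bands
#' share the excitation channel's PSF (the PSF wavelength is set by the
#' channel optics, not by the detection band), so summing the band images of
#' a noiseless scan reproduces a single full-band render exactly.
#'
#' @param ph A [phantom()].
#' @param excitation A [channel_config()] providing laser line, intensity
#'   and optics; its `emission_band` is ignored.
#' @param range A [band()]; `bandwidth` must divide its width.
#' @param bandwidth Band width in nm.
#' @inheritParams render_channel
#' @return A [spectral_stack()].
#' @export
spectral_scan <- function(ph, excitation, range = band(550, 700),
                          bandwidth = 5, detector = detector_model(),
                          seed = NULL, noise = TRUE,
                          panel = fluorophore_panel(), psf = NULL,
                          psf_mode = "gaussian") {
  if (bandwidth <= 0) stop("`bandwidth` must be positive", call. = FALSE)
  width <- range$high - range$low
  nb <- round(width / bandwidth)
  if (abs(nb * bandwidth - width) > 1e-9)
    stop("`bandwidth` must divide the scan range width", call. = FALSE)
  if (is.null(psf)) {
    cfg <- excitation$optical
    cfg$dx <- ph$voxel[1]; cfg$dy <- ph$voxel[2]; cfg$dz <- ph$voxel[3]
    psf <- make_nexciton_psf(cfg, psf_mode, auto_psf_shape(cfg, ph$dim))
  }
  wl <- seq(380, 780, by = 1)
  ## blur each label's density once; per-band images are linear combinations
  blurred <- list(); spectra <- list()
  for (lab in names(ph$density)) {
    if (all(ph$density[[lab]] == 0)) next
    fluor <- panel[[lab]]
    if (is.null(fluor))
      stop(sprintf("no fluorophore model for label '%s'", lab), call. = FALSE)
    i_eff <- excitation$laser_intensity *
      excitation_efficiency(fluor, excitation$excitation_wavelength)
    spectra[[lab]] <- emission_spectrum(fluor, i_eff, wl)
    blurred[[lab]] <- fft_convolve(ph$density[[lab]], psf)
  }
  if (!is.null(seed)) set.seed(seed)
  edges <- range$low + bandwidth * (0:nb)
  out <- array(0, dim = c(ph$dim, nb))
  for (i in seq_len(nb)) {
    bd <- band(edges[i], edges[i + 1])
    photons <- array(0, dim = ph$dim)
    for (lab in names(blurred))
      photons <- photons +
        blurred[[lab]] * band_integrate(spectra[[lab]], bd, absolute = TRUE)
    photons[photons < 0] <- 0
    out[, , , i] <- apply_detector(photons, detector, seed = NULL, noise)
  }
  spectral_stack(out, band_centers = (edges[-1] + edges[-(nb + 1)]) / 2,
                 bandwidth = bandwidth, voxel = ph$voxel,
                 meta = list(excitation = excitation$excitation_wavelength,
                             laser_intensity = excitation$laser_intensity,
                             photon_order = excitation$optical$photon_order,
                             seed = seed, noise = noise))
}

# ---- multiplexing scan plans ------------------------------------------------

#' Multiplexing scan plan for a fluorophore panel
#'
#' Returns the acquisition scheme for combining tri-exciton imaging of QD655
#' with organic fluorophores, as two consecutive scans (organics first, then
#' the high-power QDTX scan, which minimizes bleaching of the organics):
#'
#' * `DAPI + QD655 + Alexa700`: scan 1 images DAPI (Ex405/Em415-470) and
#'   Alexa700 (Ex633/Em700-750); scan 2 runs QDTX at **488 nm** excitation
#'   (Em560-610) to avoid cross-exciting DAPI.
#' * `Atto488 + QD655 + Alexa700`: scan 1 images Atto488 (Ex488/Em500-530)
#'   and Alexa700 (Ex633/Em700-750); scan 2 runs QDTX at 405 nm
#'   (Em580-610), since 488 nm would cross-excite Atto488.
#' * all four: scan 1 images the three organics; scan 2 is a 405 nm spectral
#'   scan over 430-610 nm with `unmix_required = TRUE`, because DAPI
#'   bleed-through into the QDTX band is unavoidable and must be unmixed.
#'
#' @param panel Character vector of fluorophore names; must contain
#'   `"QD655"`.
#' @return Object of class `scan_plan`: list with `scans` (ordered list of
#'   simultaneous channel descriptors) and `unmix_required`.
#' @export
plan_multiplex <- function(panel) {
  known <- c("DAPI", "Atto488", "QD655", "Alexa700")
  bad <- setdiff(panel, known)
  if (length(bad))
    stop("unknown fluorophore(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!"QD655" %in% panel)
    stop("multiplex plans require QD655", call. = FALSE)
  key <- paste(sort(unique(panel)), collapse = "+")
  ch <- function(fluor, ex, lo, hi, order = 1L, laser_pct = 10,
                 type = "image", bandwidth = NA_real_) {
    list(fluorophore = fluor, excitation = ex, em_low = lo, em_high = hi,
         photon_order = order, laser_pct = laser_pct, type = type,
         bandwidth = bandwidth)
  }
  plan <- switch(key,
    "Alexa700+DAPI+QD655" = list(
      scans = list(
        list(ch("DAPI", 405, 415, 470), ch("Alexa700", 633, 700, 750)),
        list(ch("QD655", 488, 560, 610, order = 3L, laser_pct = 30))),
      unmix_required = FALSE),
    "Alexa700+Atto488+QD655" = list(
      scans = list(
        list(ch("Atto488", 488, 500, 530), ch("Alexa700", 633, 700, 750)),
        list(ch("QD655", 405, 580, 610, order = 3L, laser_pct = 30))),
      unmix_required = FALSE),
    "Alexa700+Atto488+DAPI+QD655" = list(
      scans = list(
        list(ch("DAPI", 405, 415, 470), ch("Atto488", 488, 500, 530),
             ch("Alexa700", 633, 700, 750)),
        list(ch("QD655", 405, 430, 610, order = 3L, laser_pct = 30,
                type = "spectral", bandwidth = 10))),
      unmix_required = TRUE),
    stop("unsupported panel: ", key, call. = FALSE))
  ## invariant: simultaneous channels must not share emission bands
  for (scan in plan$scans) {
    if (length(scan) > 1L) {
      edges <- t(vapply(scan, function(s) c(s$em_low, s$em_high), numeric(2)))
      edges <- edges[order(edges[, 1]), , drop = FALSE]
      if (any(edges[-1, 1] < edges[-nrow(edges), 2]))
        stop("simultaneous channels share an emission band", call. = FALSE)
    }
  }
  structure(c(plan, list(panel = sort(unique(panel)))), class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat("<scan_plan>", paste(x$panel, collapse = " + "),
      if (x$unmix_required) "(unmixing required)" else "", "\n")
  for (i in seq_along(x$scans)) {
    cat(sprintf("  Scan %d:\n", i))
    for (s in x$scans[[i]])
      cat(sprintf("    %-8s Ex%g/Em%g-%g%s\n", s$fluorophore, s$excitation,
                  s$em_low, s$em_high,
                  if (s$type == "spectral") " (spectral scan)" else ""))
  }
  invisible(x)
}

#' Execute a multiplexing scan plan on a phantom
#'
#' Runs the plan's scans in order. Every channel render sums over *all*
#' phantom labels, so cross-excitation and bleed-through are emergent from
#' the fluorophores' excitation/emission spectra rather than assumed away.
#'
#' @param ph A [phantom()] whose labels include every plan fluorophore.
#' @param plan A [plan_multiplex()] result.
#' @inheritParams render_channel
#' @return List with `images` (named list of [image_stack()]s) and
#'   `spectral` (a [spectral_stack()] or `NULL`).
#' @export
simulate_plan <- function(ph, plan, detector = detector_model(), seed = NULL,
                          noise = TRUE, panel = fluorophore_panel(),
                          psf_mode = "gaussian") {
  stopifnot(inherits(plan, "scan_plan"))
  if (length(plan$scans) == 0L)
    return(list(images = list(), spectral = NULL))
  want <- unique(unlist(lapply(plan$scans, function(s)
    vapply(s, `[[`, "", "fluorophore"))))
  missing <- setdiff(want, names(ph$density))
  if (length(missing))
    stop("phantom lacks labels required by the plan: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  images <- list(); spectral <- NULL
  for (scan in plan$scans) {
    for (s in scan) {
      cc <- channel_config(
        name = s$fluorophore, excitation_wavelength = s$excitation,
        laser_intensity = s$laser_pct / 10,
        emission_band = band(s$em_low, s$em_high),
        optical = optical_config(
          lambda_exc = s$excitation,
          lambda_em = if (s$photon_order == 3L) NA else
            panel[[s$fluorophore]]$emission$components$center[1],
          photon_order = s$photon_order,
          dx = ph$voxel[1], dy = ph$voxel[2], dz = ph$voxel[3]))
      if (s$type == "spectral") {
        spectral <- spectral_scan(ph, cc, band(s$em_low, s$em_high),
                                  bandwidth = s$bandwidth, detector = detector,
                                  noise = noise, panel = panel,
                                  psf_mode = psf_mode)
      } else {
        images[[s$fluorophore]] <- render_channel(ph, cc, detector,
                                                  noise = noise, panel = panel,
                                                  psf_mode = psf_mode)
      }
    }
  }
  list(images = images, spectral = spectral)
}
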