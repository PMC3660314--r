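## End-to-end in-silico experiments: the resolution-enhancement study on
## filament phantoms and the spectral-scan study on QD-cluster phantoms.
## These wrap the full chain (phantom -> acquisition -> restoration ->
## metrics) under one seed, the way the corresponding bench experiments are
## run.

#' Simulated resolution-enhancement study on filament phantoms
#'
#' Generates a seeded phantom of straight 25 nm filaments, images it in the
#' conventional QD channel (order 1, 405 nm excitation, 635-675 nm
#' detection, low laser power) and the tri-exciton QDTX channel (order 3,
#' 405 nm excitation, 580-610 nm detection, high power) with Poisson and
#' detector noise, deconvolves the QDTX channel with the order-2-model
#' theoretical PSF at the QDTX wavelengths (40 Richardson-Lucy iterations,
#' estimated background), and measures Gaussian-fit FWHMs across every
#' filament in all three images.
#'
#' @param seed Integer seed controlling phantom layout and noise.
#' @param dim,voxel Grid dimensions (voxels) and voxel sizes (nm).
#' @param n_filaments Number of filaments (>= 10 recommended).
#' @param peak_counts Approximate peak signal above offset in the QD
#'   channel, counts.
#' @param iterations Richardson-Lucy iterations for the deconvolution.
#' @param detector A [detector_model()].
#' @return List with `report` (an [enhancement_report()]), `fwhm`
#'   (data.frame of per-filament FWHMs), the three [image_stack()]s and the
#'   phantom.
#' @export
simulate_enhancement_study <- function(seed = 1, dim = c(128, 128, 32),
                                       voxel = c(50, 50, 150),
                                       n_filaments = 12, peak_counts = 200,
                                       iterations = 40,
                                       detector = detector_model()) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, 3L)
  ph <- make_filaments(n = n_filaments, diameter = 25, min_separation = 800,
                       dim = dim, voxel = voxel, seed = seeds[1],
                       layout = "parallel")
  ch_qd <- channel_qd(dx = voxel[1], dy = voxel[2], dz = voxel[3])
  ch_tx <- channel_qdtx(dx = voxel[1], dy = voxel[2], dz = voxel[3])
  ## calibrate brightness so the QD channel peaks near `peak_counts`
  ref <- render_channel(ph, ch_qd, detector, noise = FALSE)
  ph <- scale_phantom(ph, peak_counts / (max(ref$data) - detector$offset))
  img_qd <- render_channel(ph, ch_qd, detector, seed = seeds[2])
  img_tx <- render_channel(ph, ch_tx, detector, seed = seeds[3])
  ## deconvolution PSF: 2-photon model at the QDTX imaging wavelengths
  cfg2 <- optical_config(lambda_exc = 405, lambda_em = 580, photon_order = 2L,
                         dx = voxel[1], dy = voxel[2], dz = voxel[3])
  psf2 <- make_nexciton_psf(cfg2, "gaussian", auto_psf_shape(cfg2, dim))
  img_dc <- cmle_deconvolve(img_tx, psf2, iterations = iterations)
  f_qd <- measure_filament_fwhms(img_qd, ph)
  f_tx <- measure_filament_fwhms(img_tx, ph)
  f_dc <- measure_filament_fwhms(img_dc, ph)
  ok <- stats::complete.cases(cbind(f_qd, f_tx, f_dc))
  rep <- enhancement_report(f_qd[ok], f_tx[ok], f_dc[ok])
  list(report = rep,
       fwhm = data.frame(qd = f_qd, qdtx = f_tx, decon = f_dc),
       qd = img_qd, qdtx = img_tx, decon = img_dc, phantom = ph)
}

#' Simulated high-power spectral scan of QD clusters
#'
#' Generates a seeded phantom of QD655 clusters, acquires a noisy spectral
#' emission scan (default 550-700 nm in 5 nm bands) at high excitation
#' intensity, forms a brightness-weighted cluster spectrum from the band
#' images, and fits three Gaussian components (inverse-variance weighted) to
#' recover the mono-, bi- and tri-exciton centers.
#'
#' @param seed Integer seed.
#' @param dim,voxel Grid dimensions and voxel sizes.
#' @param n_clusters Number of QD clusters.
#' @param intensity Relative excitation intensity (8 = 80% laser).
#' @param scan_range A [band()] for the scan.
#' @param bandwidth Band width, nm.
#' @param peak_counts Approximate peak counts above offset in the brightest
#'   band.
#' @param detector A [detector_model()].
#' @return List with `fit` (component table from
#'   [fit_spectral_components()]), `tx_center` (bluest fitted center, nm),
#'   `band_centers`, `spectrum`, and the [spectral_stack()].
#' @export
simulate_spectral_study <- function(seed = 1, dim = c(128, 128, 24),
                                    voxel = c(50, 50, 150), n_clusters = 20,
                                    intensity = 8,
                                    scan_range = band(550, 700),
                                    bandwidth = 5, peak_counts = 3000,
                                    detector = detector_model()) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, 2L)
  ph <- make_vesicles(n_small = n_clusters, small_range = c(100, 300),
                      n_hollow = 0, dim = dim, voxel = voxel,
                      seed = seeds[1])
  exc <- channel_config("QD655", 405, laser_intensity = intensity,
                        emission_band = scan_range,
                        optical = optical_config(
                          lambda_exc = 405, lambda_em = NA, photon_order = 3L,
                          dx = voxel[1], dy = voxel[2], dz = voxel[3]))
  ref <- spectral_scan(ph, exc, scan_range, bandwidth, detector,
                       noise = FALSE)
  ph <- scale_phantom(ph, peak_counts / (max(ref$data) - detector$offset))
  ss <- spectral_scan(ph, exc, scan_range, bandwidth, detector,
                      seed = seeds[2])
  nb <- dim(ss$data)[4]
  ## brightness-weighted (matched-filter) cluster spectrum
  tot <- apply(ss$data, 1:3, sum) - nb * detector$offset
  w <- pmax(tot, 0)
  if (sum(w) == 0) stop("no signal in the spectral scan", call. = FALSE)
  w <- w / sum(w)
  spec <- apply(ss$data, 4, function(b) sum(w * (b - detector$offset)))
  ## approximate shot-noise variance of the weighted band sums
  v <- pmax(spec, 0) * max(w) +
    sum(w^2) * (detector$gain + detector$read_noise_sd^2)
  fit <- fit_spectral_components(ss$band_centers, spec, weights = 1 / v)
  list(fit = fit, tx_center = fit$center[1], band_centers = ss$band_centers,
       spectrum = spec, scan = ss, phantom = ph)
}
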