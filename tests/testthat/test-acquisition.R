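# Confocal image formation: detector statistics, convolution identity,
# resolution behavior, spectral scans, and Table-style multiplexing plans.

test_that("an empty phantom images as pure offset plus noise", {
  ph <- phantom(c(32, 32, 8), c(50, 50, 150))
  det <- detector_model(offset = 10, read_noise_sd = 2)
  img <- render_channel(ph, channel_qd(), det, seed = 1)
  se <- sqrt(stats::var(as.vector(img$data)) / length(img$data))
  expect_lt(abs(mean(img$data) - det$offset), 3 * se + 1e-9)
})

test_that("a noiseless point source images as the PSF", {
  ph <- delta_phantom()
  cfg <- optical_config(lambda_exc = 405, lambda_em = 655, photon_order = 1L,
                        dx = 50, dy = 50, dz = 150)
  psf <- make_nexciton_psf(cfg, "gaussian", c(17, 17, 9))
  det <- quiet_detector()
  img <- render_channel(ph, channel_qd(), det, noise = FALSE, psf = psf)
  sig <- img$data - det$offset
  expect_equal(sig / sum(sig),
               fft_convolve(ph$density$QD655, psf) /
                 sum(fft_convolve(ph$density$QD655, psf)),
               tolerance = 1e-6)
  # and the central crop matches the PSF shape itself
  ctr <- dim(sig) %/% 2L + 1L
  crop <- sig[ctr[1] + (-8:8), ctr[2] + (-8:8), ctr[3] + (-4:4)]
  expect_equal(crop / sum(crop), psf$values / sum(psf$values),
               tolerance = 1e-6)
})

test_that("noiseless rendering is linear in emitter density", {
  ph <- make_filaments(n = 2, dim = c(48, 48, 9), voxel = c(50, 50, 150),
                       seed = 6, layout = "parallel", z_offset = 0)
  det <- quiet_detector()
  a <- render_channel(ph, channel_qd(), det, noise = FALSE)
  b <- render_channel(scale_phantom(ph, 2), channel_qd(), det, noise = FALSE)
  expect_equal(b$data - det$offset, 2 * (a$data - det$offset),
               tolerance = 1e-9)
})

test_that("the tri-exciton channel resolves a filament pair the QD channel cannot", {
  # oracle: two Gaussians separated by s show a central dip iff s > 2 sigma;
  # the spacing is chosen between the two channels' 2-sigma limits
  vox <- c(25, 25, 150)
  det <- quiet_detector()
  single <- make_filaments(n = 1, dim = c(128, 96, 9), voxel = vox, seed = 2,
                           layout = "parallel", z_offset = 0)
  fw <- vapply(list(channel_qd(dx = 25, dz = 150),
                    channel_qdtx(dx = 25, dz = 150)), function(ch) {
    img <- render_channel(single, ch, det, noise = FALSE)
    measure_filament_fwhms(img, single, method = "gaussian_fit",
                           profile_halflength = 500)
  }, numeric(1))
  sig <- fw / (2 * sqrt(2 * log(2)))
  spacing <- 25 * round(sqrt(prod(2 * sig)) / 25)  # geometric mean, on-grid
  expect_gt(spacing, 2 * sig[2])   # TX should resolve it ...
  expect_lt(spacing, 2 * sig[1])   # ... and QD should not
  pair <- make_filaments(n = 1, dim = c(128, 96, 9), voxel = vox, seed = 2,
                         layout = "pairs", pair_spacing = spacing,
                         min_separation = 1500)
  mid <- pair$geometry[[1]]$points[1, ] / 2 + pair$geometry[[2]]$points[1, ] / 2
  p0 <- c(mid[1] - 500, 0.5 * 95 * 25, mid[3])
  p1 <- c(mid[1] + 500, 0.5 * 95 * 25, mid[3])
  dip_of <- function(ch) {
    img <- render_channel(pair, ch, det, noise = FALSE)
    pr <- extract_line_profile(img, round(p0 / vox) * vox,
                               round(p1 / vox) * vox)
    v <- pr$values - det$offset
    ctr <- which.min(abs(pr$positions - max(pr$positions) / 2))
    1 - v[ctr] / max(v)
  }
  expect_gt(dip_of(channel_qdtx(dx = 25, dz = 150)), 0.1)  # clear dip
  expect_lt(dip_of(channel_qd(dx = 25, dz = 150)), 0.02)   # merged
})

test_that("detector noise shows the photon-transfer property", {
  ph <- phantom(c(32, 32, 8), c(50, 50, 150))
  ph$density$QD655[] <- 5        # uniform emitter field
  det <- detector_model(quantum_efficiency = 1, gain = 2, offset = 0,
                        read_noise_sd = 0, bit_depth = 16L)
  img <- render_channel(ph, channel_qd(), det, seed = 42)
  m <- mean(img$data); v <- stats::var(as.vector(img$data))
  expect_equal(v / m, det$gain, tolerance = 0.1)
})

test_that("spectral scans have the right band count and are additive", {
  ph <- make_vesicles(n_small = 3, small_range = c(150, 300), n_hollow = 0,
                      dim = c(32, 32, 8), voxel = c(50, 50, 150), seed = 4)
  det <- quiet_detector()
  exc <- channel_config("QD655", 405, laser_intensity = 5,
                        emission_band = band(550, 700),
                        optical = optical_config(lambda_exc = 405,
                                                 lambda_em = NA,
                                                 photon_order = 3L,
                                                 dx = 50, dy = 50, dz = 150))
  ss <- spectral_scan(ph, exc, band(550, 700), 5, det, noise = FALSE)
  expect_equal(dim(ss$data)[4], 30)
  expect_error(spectral_scan(ph, exc, band(550, 700), 7), "divide")
  expect_error(spectral_scan(ph, exc, band(550, 700), -5), "positive")
  # bands sum to the single full-band render (identical PSF settings)
  full <- render_channel(ph, channel_config(
    "QD655", 405, laser_intensity = 5, emission_band = band(550, 700),
    optical = exc$optical), det, noise = FALSE)
  summed <- apply(ss$data - det$offset, 1:3, sum) + det$offset
  expect_equal(summed, full$data,
               tolerance = 1e-6 * max(full$data) / mean(full$data))
})

test_that("a high-power cluster scan carries a tri-exciton component near 590", {
  st <- simulate_spectral_study(seed = 3, dim = c(64, 64, 16),
                                n_clusters = 6, peak_counts = 3000)
  expect_gt(st$tx_center, 585)
  expect_lt(st$tx_center, 595)
})

test_that("plan_multiplex reproduces the reference acquisition schemes exactly", {
  p1 <- plan_multiplex(c("DAPI", "QD655", "Alexa700"))
  expect_false(p1$unmix_required)
  expect_equal(length(p1$scans), 2)
  qdtx <- p1$scans[[2]][[1]]
  expect_equal(qdtx$excitation, 488)    # 488 nm avoids DAPI cross-excitation
  expect_equal(c(qdtx$em_low, qdtx$em_high), c(560, 610))
  dapi <- p1$scans[[1]][[1]]
  expect_equal(c(dapi$excitation, dapi$em_low, dapi$em_high), c(405, 415, 470))
  a700 <- p1$scans[[1]][[2]]
  expect_equal(c(a700$excitation, a700$em_low, a700$em_high), c(633, 700, 750))

  p2 <- plan_multiplex(c("Atto488", "QD655", "Alexa700"))
  qdtx2 <- p2$scans[[2]][[1]]
  expect_equal(qdtx2$excitation, 405)
  expect_equal(c(qdtx2$em_low, qdtx2$em_high), c(580, 610))
  a488 <- p2$scans[[1]][[1]]
  expect_equal(c(a488$excitation, a488$em_low, a488$em_high), c(488, 500, 530))

  p3 <- plan_multiplex(c("DAPI", "Atto488", "QD655", "Alexa700"))
  expect_true(p3$unmix_required)
  expect_equal(length(p3$scans[[1]]), 3)
  sc <- p3$scans[[2]][[1]]
  expect_equal(sc$type, "spectral")
  expect_equal(c(sc$excitation, sc$em_low, sc$em_high), c(405, 430, 610))

  expect_error(plan_multiplex(c("DAPI", "Alexa700")), "QD655")
  expect_error(plan_multiplex(c("QD655", "FITC")), "unknown")
  expect_error(plan_multiplex(c("QD655", "Atto488")), "unsupported")
})

test_that("cross-excitation bleed-through is emergent, not assumed", {
  dims <- c(32, 32, 8); vox <- c(50, 50, 150)
  ph <- phantom(dims, vox, labels = c("DAPI", "QD655"))
  ph$density$DAPI[8:12, 8:12, 4] <- 100
  ph$density$QD655[20:24, 20:24, 4] <- 100
  det <- quiet_detector()
  qdtx_at <- function(exc_nm) {
    channel_config("QD655", exc_nm, laser_intensity = 3,
                   emission_band = band(580, 610),
                   optical = optical_config(lambda_exc = exc_nm,
                                            lambda_em = NA, photon_order = 3L,
                                            dx = 50, dy = 50, dz = 150))
  }
  dapi_only <- phantom(dims, vox, labels = c("DAPI", "QD655"))
  dapi_only$density$DAPI <- ph$density$DAPI
  qd_only <- phantom(dims, vox, labels = c("DAPI", "QD655"))
  qd_only$density$QD655 <- ph$density$QD655
  # at 405 nm DAPI bleeds into the QDTX band ...
  bleed405 <- sum(render_channel(dapi_only, qdtx_at(405), det,
                                 noise = FALSE)$data - det$offset)
  expect_gt(bleed405, 0)
  # ... at 488 nm it is below 1% of the QD signal (DAPI is not excited)
  bleed488 <- sum(render_channel(dapi_only, qdtx_at(488), det,
                                 noise = FALSE)$data - det$offset)
  signal488 <- sum(render_channel(qd_only, qdtx_at(488), det,
                                  noise = FALSE)$data - det$offset)
  expect_lt(bleed488 / signal488, 0.01)
  expect_lt(excitation_efficiency(fluorophore_panel()$DAPI, 488), 0.01)
})

test_that("simulate_plan runs full plans and guards missing labels", {
  dims <- c(32, 32, 8); vox <- c(50, 50, 150)
  ph <- phantom(dims, vox, labels = c("DAPI", "QD655", "Alexa700"))
  ph$density$DAPI[10:14, 10:14, 4] <- 50
  ph$density$QD655[20:26, 8:12, 4] <- 50
  ph$density$Alexa700[6:10, 20:24, 4] <- 50
  det <- quiet_detector()
  plan <- plan_multiplex(c("DAPI", "QD655", "Alexa700"))
  out <- simulate_plan(ph, plan, det, seed = 2, noise = FALSE)
  expect_setequal(names(out$images), c("DAPI", "Alexa700", "QD655"))
  expect_null(out$spectral)
  # each channel sees its own structure brightest
  dapi_sig <- out$images$DAPI$data - det$offset
  expect_gt(sum(dapi_sig[10:14, 10:14, 4]), sum(dapi_sig[6:10, 20:24, 4]))
  # missing labels are reported by name
  ph2 <- phantom(dims, vox, labels = "QD655")
  expect_error(simulate_plan(ph2, plan, det), "DAPI")
  # empty plan gives empty output
  empty <- structure(list(scans = list(), unmix_required = FALSE,
                          panel = character(0)), class = "scan_plan")
  out0 <- simulate_plan(ph, empty, det)
  expect_equal(out0$images, list())
  expect_null(out0$spectral)
})

test_that("the four-color plan yields a spectral stack that unmixes DAPI from QDTX", {
  dims <- c(32, 32, 8); vox <- c(50, 50, 150)
  ph <- phantom(dims, vox, labels = c("DAPI", "Atto488", "QD655", "Alexa700"))
  ph$density$DAPI[8:14, 8:14, 4] <- 200
  ph$density$Atto488[4:8, 20:26, 4] <- 200
  ph$density$QD655[20:26, 8:14, 4] <- 200
  ph$density$Alexa700[20:26, 20:26, 4] <- 200
  det <- detector_model(offset = 0, read_noise_sd = 0)
  plan <- plan_multiplex(c("DAPI", "Atto488", "QD655", "Alexa700"))
  out <- simulate_plan(ph, plan, det, noise = FALSE)
  expect_s3_class(out$spectral, "spectral_stack")
  panel <- fluorophore_panel()
  refs <- list(DAPI = emission_spectrum(panel$DAPI, 1),
               QD655 = emission_spectrum(panel$QD655, 3))
  un <- linear_unmix(out$spectral, refs)
  # DAPI abundance localizes on the DAPI structure, QD on the QD structure
  expect_gt(mean(un$abundance$DAPI[8:14, 8:14, 4]),
            10 * mean(un$abundance$DAPI[20:26, 8:14, 4]))
  expect_gt(mean(un$abundance$QD655[20:26, 8:14, 4]),
            10 * mean(un$abundance$QD655[8:14, 8:14, 4]))
})
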