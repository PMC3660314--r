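# PSF models: Airy unit, excitation/detection/n-exciton PSFs, FWHM and
# Nyquist sampling.

test_that("airy_unit_diameter matches 1.22 lambda/NA and rejects bad input", {
  expect_equal(airy_unit_diameter(655, 1.4), 1.22 * 655 / 1.4)
  expect_equal(round(airy_unit_diameter(655, 1.4), 1), 570.8)
  expect_equal(round(airy_unit_diameter(580, 1.4), 1), 505.4)
  expect_error(airy_unit_diameter(655, 0), "positive")
  expect_error(airy_unit_diameter(-5, 1.4), "positive")
})

test_that("optical_config enforces its invariants", {
  expect_error(optical_config(na = 1.6, immersion_index = 1.515), "na")
  expect_error(optical_config(lambda_exc = 250), "300")
  expect_error(optical_config(pinhole_au = 0), "pinhole")
  expect_error(optical_config(dx = -1), "voxel")
  expect_error(optical_config(photon_order = 0), "photon_order")
})

test_that("gaussian excitation PSF hits the closed-form widths", {
  ex <- make_excitation_psf(fine_cfg(), "gaussian", fine_shape)
  expect_equal(psf_fwhm(ex, "x"), 0.51 * 405 / 1.4, tolerance = 0.005)
  expect_equal(psf_fwhm(ex, "z"),
               0.88 * 405 / (1.515 - sqrt(1.515^2 - 1.4^2)),
               tolerance = 0.005)
  # lateral FWHM decreases with NA
  ex_lo <- make_excitation_psf(
    optical_config(na = 1.0, lambda_exc = 405, dx = 10, dy = 10, dz = 30),
    "gaussian", fine_shape)
  expect_gt(psf_fwhm(ex_lo, "x"), psf_fwhm(ex, "x"))
})

test_that("gaussian and scalar-diffraction lateral FWHMs agree within 10%", {
  for (lam in c(405, 580)) {
    cfg <- fine_cfg(lambda_exc = lam)
    g <- psf_fwhm(make_excitation_psf(cfg, "gaussian", c(129, 129, 5)), "x")
    s <- psf_fwhm(make_excitation_psf(cfg, "scalar_diffraction",
                                      c(129, 129, 5)), "x")
    expect_lt(abs(g - s) / s, 0.10)
  }
})

test_that("every PSF is normalized, symmetric, and peaked at its center", {
  shapes <- c(33, 33, 17)
  cfgs <- list(fine_cfg(), fine_cfg(photon_order = 3L, lambda_em = NA))
  for (cfg in cfgs) for (mode in c("gaussian", "scalar_diffraction")) {
    p <- make_nexciton_psf(cfg, mode, shapes)
    expect_equal(sum(p$values), 1, tolerance = 1e-6)
    flipped <- p$values[rev(seq_len(shapes[1])), rev(seq_len(shapes[2])),
                        rev(seq_len(shapes[3]))]
    expect_lt(max(abs(p$values - flipped)), 1e-6)
    expect_equal(p$center, (shapes %/% 2L) + 1L)
  }
})

test_that("detection PSF respects the pinhole: point limit and monotonic growth", {
  fw_em <- 0.51 * 655 / 1.4
  d_point <- make_detection_psf(fine_cfg(pinhole_au = 0.01), "gaussian",
                                c(129, 129, 5))
  expect_equal(psf_fwhm(d_point, "x"), fw_em, tolerance = 0.02)
  fwhms <- vapply(c(0.7, 1.2, 2.0), function(au)
    psf_fwhm(make_detection_psf(fine_cfg(pinhole_au = au), "gaussian",
                                c(129, 129, 5)), "x"), numeric(1))
  expect_true(all(diff(fwhms) > 0))
  # and wider emission wavelength gives a wider detection PSF
  d_red <- make_detection_psf(fine_cfg(lambda_em = 700), "gaussian",
                              c(129, 129, 5))
  d_blue <- make_detection_psf(fine_cfg(lambda_em = 580), "gaussian",
                               c(129, 129, 5))
  expect_gt(psf_fwhm(d_red, "x"), psf_fwhm(d_blue, "x"))
  expect_error(make_detection_psf(fine_cfg(lambda_em = NA)), "lambda_em")
})

test_that("n-exciton PSF is the excitation^n x detection product", {
  shape <- c(65, 65, 33)
  cfg1 <- fine_cfg(lambda_em = NA, photon_order = 1L)
  p1 <- make_nexciton_psf(cfg1, "gaussian", shape)
  ex <- make_excitation_psf(cfg1, "gaussian", shape)
  det <- make_detection_psf(fine_cfg(lambda_em = 655), "gaussian", shape)
  prod <- ex$values * det$values
  expect_equal(p1$values, prod / sum(prod), tolerance = 1e-10)
  # cubing a Gaussian divides its FWHM by sqrt(3), exactly
  cube <- new_psf(ex$values^3, ex$dx, ex$dy, ex$dz)
  expect_equal(psf_fwhm(ex, "x") / psf_fwhm(cube, "x"), sqrt(3),
               tolerance = 0.005)
  bad <- cfg1; bad$photon_order <- 4L
  expect_error(make_nexciton_psf(bad), "unsupported")
})

test_that("bi- and tri-exciton PSFs resemble each other more than the mono PSF", {
  shape <- c(65, 65, 33)
  ps <- lapply(1:3, function(n)
    make_nexciton_psf(fine_cfg(lambda_em = NA, photon_order = n),
                      "gaussian", shape)$values)
  d32 <- sum(abs(ps[[3]] - ps[[2]]))
  d31 <- sum(abs(ps[[3]] - ps[[1]]))
  d21 <- sum(abs(ps[[2]] - ps[[1]]))
  expect_lt(d32, d31)
  expect_lt(d32, d21)
})

test_that("psf_fwhm interpolates correctly and guards its preconditions", {
  # Gaussian sigma = 100 nm sampled at 10 nm -> 2 sqrt(2 ln 2) * 100 = 235.48
  x <- seq(-500, 500, by = 10)
  prof <- exp(-x^2 / (2 * 100^2))
  expect_equal(qdti:::profile_fwhm(x, prof), 2 * sqrt(2 * log(2)) * 100,
               tolerance = 1 / 235)
  # intensity scaling leaves the FWHM unchanged
  expect_equal(qdti:::profile_fwhm(x, 7.3 * prof),
               qdti:::profile_fwhm(x, prof))
  expect_error(qdti:::profile_fwhm(x[1:3], prof[1:3]), "5 samples")
  expect_error(qdti:::profile_fwhm(x, seq_along(x)), "boundary")
})

test_that("nyquist_sampling derives admissible spacings from the PSF itself", {
  cfg <- optical_config(lambda_exc = 405, lambda_em = 655, photon_order = 1L,
                        dx = 20, dy = 20, dz = 40)
  p <- make_nexciton_psf(cfg, "scalar_diffraction", c(65, 65, 65))
  ny <- nyquist_sampling(p)
  expect_equal(unname(ny["dz_max"]), psf_fwhm(p, "z") / 2.3)
  expect_gte(ny[["dz_max"]], 100)        # the 0.1-0.2 um z-step is admissible
  expect_lt(ny[["dx_max"]], ny[["dz_max"]])
  # doubling all wavelengths doubles both outputs in gaussian mode
  p1 <- make_nexciton_psf(optical_config(lambda_exc = 350, lambda_em = 375,
                                         dx = 20, dy = 20, dz = 40),
                          "gaussian", c(65, 65, 65))
  p2 <- make_nexciton_psf(optical_config(lambda_exc = 700, lambda_em = 750,
                                         dx = 40, dy = 40, dz = 80),
                          "gaussian", c(65, 65, 65))
  expect_equal(nyquist_sampling(p2), 2 * nyquist_sampling(p1),
               tolerance = 0.02)
})
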