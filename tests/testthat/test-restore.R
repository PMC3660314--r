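# Richardson-Lucy deconvolution, spectral unmixing, artifact scoring.

delta_psf <- function(shape = c(9, 9, 5), vox = c(50, 50, 150)) {
  v <- array(0, dim = shape)
  v[shape[1] %/% 2L + 1L, shape[2] %/% 2L + 1L, shape[3] %/% 2L + 1L] <- 1
  new_psf(v, vox[1], vox[2], vox[3])
}

blur_cfg <- optical_config(lambda_exc = 405, lambda_em = 655,
                           photon_order = 1L, dx = 50, dy = 50, dz = 150)

test_that("deconvolving with a delta PSF returns the background-subtracted input", {
  set.seed(1)
  x <- array(stats::runif(24 * 24 * 8, 5, 50), dim = c(24, 24, 8))
  img <- image_stack(x, c(50, 50, 150))
  out <- cmle_deconvolve(img, delta_psf(), iterations = 10, background = 5)
  expect_equal(out$data, pmax(x - 5, 0), tolerance = 1e-9)
})

test_that("RL iterations conserve flux and non-negativity with zero background", {
  ph <- delta_phantom(dim = c(32, 32, 8))
  psf <- make_nexciton_psf(blur_cfg, "gaussian", c(17, 17, 7))
  blurred <- fft_convolve(ph$density$QD655, psf)
  out <- cmle_deconvolve(blurred, psf, iterations = 15, background = 0,
                         trace = TRUE)
  tr <- attr(out, "trace")
  expect_equal(tr$flux / sum(blurred), rep(1, 15), tolerance = 1e-6)
  expect_true(all(tr$minimum >= 0))
})

test_that("RL sharpens a blurred point and filaments monotonically", {
  ph <- delta_phantom(dim = c(33, 33, 9))
  psf <- make_nexciton_psf(blur_cfg, "gaussian", c(17, 17, 7))
  blurred <- image_stack(fft_convolve(ph$density$QD655, psf), c(50, 50, 150))
  fw_of <- function(arr) {
    ctr <- which(arr == max(arr), arr.ind = TRUE)[1, ]
    qdti:::profile_fwhm(seq_len(dim(arr)[1]) * 50, arr[, ctr[2], ctr[3]])
  }
  fw_in <- fw_of(blurred$data)
  fws <- vapply(c(5, 15, 40), function(k)
    fw_of(cmle_deconvolve(blurred, psf, iterations = k,
                          background = 0)$data), numeric(1))
  expect_true(all(fws < fw_in))
  expect_true(all(diff(fws) < 0))
})

test_that("deconvolution guards degenerate inputs", {
  psf <- make_nexciton_psf(blur_cfg, "gaussian", c(9, 9, 5))
  zero <- image_stack(array(0, c(16, 16, 6)), c(50, 50, 150))
  expect_warning(out <- cmle_deconvolve(zero, psf), "all-zero")
  expect_equal(out$data, zero$data)
  img <- image_stack(array(1, c(16, 16, 6)), c(25, 25, 150))
  expect_error(cmle_deconvolve(img, psf), "voxel sizes differ")
})

test_that("2-photon and 3-photon deconvolution models can be compared by artifact score", {
  # the harness of the model comparison: both runs complete under identical
  # iterations/background and yield finite periodicity scores
  set.seed(7)
  ph <- make_filaments(n = 2, dim = c(48, 48, 8), voxel = c(50, 50, 150),
                       seed = 7, layout = "parallel", z_offset = 0)
  det <- detector_model()
  ref <- render_channel(ph, channel_qdtx(), det, noise = FALSE)
  ph <- scale_phantom(ph, 200 / (max(ref$data) - det$offset))
  img <- render_channel(ph, channel_qdtx(), det, seed = 8)
  mk <- function(order, lam) {
    cfg <- optical_config(lambda_exc = 405, lambda_em = lam,
                          photon_order = order, dx = 50, dy = 50, dz = 150)
    make_nexciton_psf(cfg, "gaussian", c(17, 17, 7))
  }
  scores <- vapply(list(mk(2L, 580), mk(3L, 580)), function(p) {
    dec <- cmle_deconvolve(img, p, iterations = 20)
    mask <- dec$data <= stats::quantile(dec$data, 0.6)
    periodicity_score(dec$data, mask)
  }, numeric(1))
  expect_true(all(is.finite(scores)))
  expect_true(all(scores >= 1))
})

test_that("noiseless unmixing is exact and a self-reference gives unit abundance", {
  panel <- fluorophore_panel()
  refs <- list(DAPI = emission_spectrum(panel$DAPI, 1),
               QD655 = emission_spectrum(panel$QD655, 3))
  nb <- 18; bw <- 10
  centers <- seq(435, by = bw, length.out = nb)
  sig <- vapply(refs, function(r) vapply(seq_len(nb), function(i)
    band_integrate(r, band(centers[i] - 5, centers[i] + 5), absolute = TRUE),
    numeric(1)), numeric(nb))
  d <- c(6, 6, 2)
  set.seed(3)
  a_true <- list(DAPI = array(stats::runif(prod(d), 0, 50), d),
                 QD655 = array(stats::runif(prod(d), 0, 50), d))
  data4 <- array(0, c(d, nb))
  for (i in seq_len(nb))
    data4[, , , i] <- a_true$DAPI * sig[i, 1] + a_true$QD655 * sig[i, 2]
  st <- spectral_stack(data4, centers, bw, c(50, 50, 150))
  un <- linear_unmix(st, refs)
  expect_equal(un$abundance$DAPI, a_true$DAPI, tolerance = 1e-6)
  expect_equal(un$abundance$QD655, a_true$QD655, tolerance = 1e-6)
  expect_lt(max(un$residual), 1e-8 * max(data4))
  # single self-reference: abundance 1 everywhere, zero residual
  one <- array(0, c(d, nb))
  for (i in seq_len(nb)) one[, , , i] <- sig[i, 2]
  st1 <- spectral_stack(one, centers, bw, c(50, 50, 150))
  un1 <- linear_unmix(st1, refs["QD655"])
  expect_equal(un1$abundance$QD655, array(1, d), tolerance = 1e-9)
  expect_lt(max(un1$residual), 1e-9)
})

test_that("unmixing of Poisson-noisy mixtures stays within 10% median error", {
  panel <- fluorophore_panel()
  refs <- list(DAPI = emission_spectrum(panel$DAPI, 1),
               QD655 = emission_spectrum(panel$QD655, 3))
  nb <- 18; bw <- 10
  centers <- seq(435, by = bw, length.out = nb)
  sig <- vapply(refs, function(r) vapply(seq_len(nb), function(i)
    band_integrate(r, band(centers[i] - 5, centers[i] + 5), absolute = TRUE),
    numeric(1)), numeric(nb))
  d <- c(12, 12, 2)
  set.seed(11)
  ## abundance scale chosen so the typical voxel's brightest band holds
  ## ~100 counts
  amp <- 100 / max(sig) / 0.65
  a_true <- list(DAPI = array(stats::runif(prod(d), 0.3, 1) * amp, d),
                 QD655 = array(stats::runif(prod(d), 0.3, 1) * amp, d))
  data4 <- array(0, c(d, nb))
  for (i in seq_len(nb)) {
    lam <- a_true$DAPI * sig[i, 1] + a_true$QD655 * sig[i, 2]
    data4[, , , i] <- array(stats::rpois(prod(d), lam), d)
  }
  st <- spectral_stack(data4, centers, bw, c(50, 50, 150))
  un <- linear_unmix(st, refs)
  rel <- c(abs(un$abundance$DAPI - a_true$DAPI) / a_true$DAPI,
           abs(un$abundance$QD655 - a_true$QD655) / a_true$QD655)
  expect_lt(stats::median(rel), 0.10)
})

test_that("rank-deficient references are rejected with the offending pair named", {
  sp <- emission_spectrum(fluorophore_panel()$QD655, 2)
  st <- spectral_stack(array(1, c(4, 4, 2, 10)), seq(555, by = 10,
                                                     length.out = 10), 10,
                       c(50, 50, 150))
  expect_error(linear_unmix(st, list(a = sp, b = sp)),
               "rank deficient.*[ab], [ab]")
})

test_that("periodicity score flags planted periodic patterns, not white noise", {
  set.seed(21)
  d <- c(48, 48, 16)
  noise <- array(stats::rnorm(prod(d), 100, 10), d)
  mask <- array(TRUE, d)
  s_white <- periodicity_score(noise, mask)
  expect_lt(s_white, 3)
  xg <- array(rep(seq_len(d[1]), times = prod(d[2:3])), d)
  planted <- noise + 0.1 * 100 * sin(2 * pi * xg / 8)  # 10% of mean intensity
  s_plant <- periodicity_score(planted, mask)
  expect_gt(s_plant, 5 * s_white)
  # invariant to intensity scaling
  expect_equal(periodicity_score(noise * 37, mask), s_white, tolerance = 1e-9)
  small_mask <- array(FALSE, d); small_mask[1:2, 1:2, 1] <- TRUE
  expect_error(periodicity_score(noise, small_mask), "mask")
})
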