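# Shared fixtures: fine-grid optical configs for PSF metrology and a small
# noiseless detector. All fixtures are built in code.

fine_cfg <- function(lambda_exc = 405, lambda_em = 655, photon_order = 1L,
                     pinhole_au = 0.7) {
  optical_config(lambda_exc = lambda_exc, lambda_em = lambda_em,
                 photon_order = photon_order, pinhole_au = pinhole_au,
                 dx = 10, dy = 10, dz = 30)
}

fine_shape <- c(129, 129, 65)

quiet_detector <- function(gain = 1) {
  detector_model(quantum_efficiency = 0.8, gain = gain, offset = 10,
                 read_noise_sd = 0, bit_depth = 16L)
}

## phantom with a single off-center point emitter
delta_phantom <- function(dim = c(33, 33, 17), voxel = c(50, 50, 150),
                          label = "QD655") {
  ph <- phantom(dim, voxel, label)
  ctr <- dim %/% 2L + 1L
  ph$density[[label]][ctr[1], ctr[2], ctr[3]] <- 1000
  ph
}

## analytic Gaussian line profile
gauss_profile <- function(sigma = 76.5, spacing = 10, halfwidth = 400,
                          amp = 1000, baseline = 0, mu = 0) {
  x <- seq(-halfwidth, halfwidth, by = spacing)
  list(positions = x - min(x),
       values = amp * exp(-(x - mu)^2 / (2 * sigma^2)) + baseline)
}
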