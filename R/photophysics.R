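#' Multi-exciton emission model
#'
#' Describes the emission of a fluorophore as a sum of Gaussian spectral
#' components, each tied to an exciton order. For QD655 the mono- (MX), bi-
#' (BX) and tri-exciton (TX) components are centred at 655, 620 and 590 nm
#' and their populations grow with the 1st, 2nd and 3rd power of the
#' excitation intensity before saturation.
#'
#' Component widths are not measured quantities; the defaults (30/35/40 nm
#' FWHM) are typical for QD655 and are configurable. Relative yields at
#' saturation default to 1:0.15:0.05 (MX:BX:TX), a calibration choice that
#' makes the blue shoulder emerge between low and high laser settings.
#'
#' @param components `data.frame` with columns `label`, `center` (nm),
#'   `fwhm` (nm), `exponent` (integer power law) and `yield`.
#' @param saturation_intensity Saturation constant of the excitation power
#'   law, in relative intensity units.
#' @return Object of class `exciton_model`.
#' @examples
#' m <- exciton_model()
#' exciton_weights(0.5, m)
#' @export
exciton_model <- function(components = data.frame(
                            label = c("TX", "BX", "MX"),
                            center = c(590, 620, 655),
                            fwhm = c(40, 35, 30),
                            exponent = c(3L, 2L, 1L),
                            yield = c(0.05, 0.15, 1)),
                          saturation_intensity = 1) {
  stopifnot(is.data.frame(components),
            all(c("label", "center", "fwhm", "exponent", "yield") %in%
                  names(components)))
  if (any(components$yield < 0)) stop("yields must be >= 0", call. = FALSE)
  if (any(components$fwhm <= 0)) stop("spectral FWHMs must be positive", call. = FALSE)
  ## multi-exciton components must be ordered blue to red with rising order
  for (lab in c("MX", "BX", "TX")) {
    i <- match(lab, components$label)
    if (!is.na(i)) {
      want <- c(MX = 1L, BX = 2L, TX = 3L)[[lab]]
      if (components$exponent[i] != want)
        stop(sprintf("component %s must have power exponent %d", lab, want),
             call. = FALSE)
    }
  }
  ord <- match(c("TX", "BX", "MX"), components$label)
  ord <- ord[!is.na(ord)]
  if (length(ord) > 1L && is.unsorted(components$center[ord], strictly = TRUE))
    stop("exciton centers must be ordered TX < BX < MX", call. = FALSE)
  if (saturation_intensity <= 0)
    stop("`saturation_intensity` must be positive", call. = FALSE)
  structure(list(components = components,
                 saturation_intensity = saturation_intensity),
            class = "exciton_model")
}

#' @export
print.exciton_model <- function(x, ...) {
  cat("<exciton_model> I_sat =", x$saturation_intensity, "\n")
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Exciton-state weights at a given excitation intensity
#'
#' Each component's weight is `yield * (I / (I + I_sat))^exponent`: a
#' saturating power law, so the tri-exciton population scales with the third
#' power of intensity well below saturation and is bounded above. Weights are
#' not normalized - absolute brightness matters.
#'
#' @param intensity Excitation intensity in relative units (>= 0).
#' @param model An [exciton_model()].
#' @return Named numeric vector of weights, one per component.
#' @export
exciton_weights <- function(intensity, model = exciton_model()) {
  if (!is.numeric(intensity) || intensity < 0)
    stop("`intensity` must be non-negative", call. = FALSE)
  s <- intensity / (intensity + model$saturation_intensity)
  w <- model$components$yield * s^model$components$exponent
  stats::setNames(w, model$components$label)
}

# ---- Spectrum container -----------------------------------------------------

#' Spectrum object
#'
#' Relative photon flux density per nm on a strictly increasing wavelength
#' grid.
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param values Non-negative intensities (photons/nm, relative).
#' @return Object of class `qd_spectrum`.
#' @export
qd_spectrum <- function(wavelengths, values) {
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("spectrum values must be non-negative", call. = FALSE)
  if (length(wavelengths) != length(values))
    stop("grid and values differ in length", call. = FALSE)
  structure(list(wavelengths = wavelengths, values = values),
            class = "qd_spectrum")
}

#' @export
print.qd_spectrum <- function(x, ...) {
  cat(sprintf("<qd_spectrum> %d samples, %g-%g nm, total %.4g\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              trapz_full(x$wavelengths, x$values)))
  invisible(x)
}

#' Emission spectrum at a given excitation intensity
#'
#' Sum of the model's Gaussian spectral components with amplitudes (areas)
#' given by [exciton_weights()].
#'
#' @param model An [exciton_model()] or [fluorophore_model()].
#' @param intensity Excitation intensity in relative units.
#' @param wavelengths Wavelength grid (nm); default 1 nm steps over
#'   430-750 nm.
#' @return A [qd_spectrum()].
#' @export
emission_spectrum <- function(model, intensity,
                              wavelengths = seq(430, 750, by = 1)) {
  if (inherits(model, "fluorophore_model")) model <- model$emission
  stopifnot(inherits(model, "exciton_model"))
  w <- exciton_weights(intensity, model)
  v <- numeric(length(wavelengths))
  for (i in seq_len(nrow(model$components))) {
    sig <- model$components$fwhm[i] / (2 * sqrt(2 * log(2)))
    v <- v + w[i] / (sig * sqrt(2 * pi)) *
      exp(-(wavelengths - model$components$center[i])^2 / (2 * sig^2))
  }
  qd_spectrum(wavelengths, v)
}

# ---- Band integration -------------------------------------------------------

#' Emission band
#'
#' @param low,high Band edges in nm, `low < high`.
#' @return Object of class `band`.
#' @export
band <- function(low, high) {
  if (!is.numeric(low) || !is.numeric(high) || low >= high)
    stop("band requires `low < high`", call. = FALSE)
  structure(list(low = low, high = high), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> %g-%g nm\n", x$low, x$high)); invisible(x)
}

## trapezoid rule over the whole grid
trapz_full <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

## trapezoid rule over [lo, hi] with linear interpolation at the edges;
## additive over adjacent subintervals by construction
trapz_interval <- function(x, y, lo, hi) {
  ylo <- stats::approx(x, y, xout = lo)$y
  yhi <- stats::approx(x, y, xout = hi)$y
  inside <- which(x > lo & x < hi)
  xs <- c(lo, x[inside], hi)
  ys <- c(ylo, y[inside], yhi)
  trapz_full(xs, ys)
}

#' Fraction of emitted photons within a detection band
#'
#' Trapezoidal integral of the spectrum over the band divided by the integral
#' over the full grid (or the absolute band integral when `absolute = TRUE`).
#'
#' @param spectrum A [qd_spectrum()].
#' @param bd A [band()] lying within the spectrum grid.
#' @param absolute Return the unnormalized band integral instead of the
#'   fraction.
#' @return Dimensionless photon fraction (or absolute integral).
#' @export
band_integrate <- function(spectrum, bd, absolute = FALSE) {
  stopifnot(inherits(spectrum, "qd_spectrum"), inherits(bd, "band"))
  wl <- spectrum$wavelengths
  if (bd$low < min(wl) || bd$high > max(wl))
    stop(sprintf("band %g-%g nm lies outside the spectrum grid %g-%g nm",
                 bd$low, bd$high, min(wl), max(wl)), call. = FALSE)
  num <- trapz_interval(wl, spectrum$values, bd$low, bd$high)
  if (absolute) return(num)
  num / trapz_full(wl, spectrum$values)
}

# ---- Fluorophore registry ---------------------------------------------------

#' Fluorophore model (emission components + excitation spectrum)
#'
#' Joins an emission [exciton_model()] with an excitation-efficiency
#' spectrum: either a Gaussian (`list(type = "gaussian", center, fwhm)`) or a
#' tabulated curve (`list(type = "table", wavelength, efficiency)`).
#'
#' @param name Fluorophore name.
#' @param emission An [exciton_model()].
#' @param excitation Excitation spectrum description (see Details).
#' @return Object of class `fluorophore_model`.
#' @export
fluorophore_model <- function(name, emission, excitation) {
  stopifnot(is.character(name), inherits(emission, "exciton_model"),
            is.list(excitation),
            excitation$type %in% c("gaussian", "table"))
  structure(list(name = name, emission = emission, excitation = excitation),
            class = "fluorophore_model")
}

## single-band organic dye as a fluorophore_model
organic_dye <- function(name, em_center, em_fwhm, exc_center, exc_fwhm) {
  fluorophore_model(
    name,
    exciton_model(data.frame(label = name, center = em_center,
                             fwhm = em_fwhm, exponent = 1L, yield = 1),
                  saturation_intensity = 1),
    list(type = "gaussian", center = exc_center, fwhm = exc_fwhm))
}

#' QD655 fluorophore model
#'
#' QD655 with MX/BX/TX emission components and a tabulated, monotonically
#' decreasing excitation-efficiency curve (unit efficiency at/below 405 nm,
#' still clearly non-zero at 488 and 561 nm). The table is an analytic
#' approximation shipped with the package, not a digitized measurement.
#'
#' @param ... Passed to [exciton_model()] to override components or
#'   saturation.
#' @return A [fluorophore_model()].
#' @export
qd655_model <- function(...) {
  wl <- seq(300, 650, by = 5)
  eff <- pmin(1, exp(-(wl - 405) / 90))
  fluorophore_model("QD655", exciton_model(...),
                    list(type = "table", wavelength = wl, efficiency = eff))
}

#' Standard fluorophore panel
#'
#' The four labels used in multiplexed tri-exciton imaging: DAPI, Atto488,
#' QD655 and Alexa700. Organic dyes are single-component order-1 emitters
#' with Gaussian excitation and emission spectra (approximate catalogue
#' values).
#'
#' @return Named list of [fluorophore_model()] objects.
#' @export
fluorophore_panel <- function() {
  list(
    DAPI = organic_dye("DAPI", em_center = 461, em_fwhm = 100,
                       exc_center = 358, exc_fwhm = 60),
    Atto488 = organic_dye("Atto488", em_center = 523, em_fwhm = 35,
                          exc_center = 501, exc_fwhm = 60),
    QD655 = qd655_model(),
    Alexa700 = organic_dye("Alexa700", em_center = 723, em_fwhm = 40,
                           exc_center = 696, exc_fwhm = 110))
}

#' Excitation efficiency of a fluorophore at a laser line
#'
#' @param fluor A [fluorophore_model()].
#' @param lambda Laser wavelength (nm).
#' @return Efficiency in `[0, 1]` relative to the fluorophore's peak.
#' @export
excitation_efficiency <- function(fluor, lambda) {
  stopifnot(inherits(fluor, "fluorophore_model"))
  ex <- fluor$excitation
  if (ex$type == "gaussian") {
    exp(-4 * log(2) * (lambda - ex$center)^2 / ex$fwhm^2)
  } else {
    stats::approx(ex$wavelength, ex$efficiency, xout = lambda, rule = 2)$y
  }
}

# ---- Spectral decomposition -------------------------------------------------

#' Fit Gaussian spectral components to a measured spectrum
#'
#' Least-squares fit of a sum of Gaussian components (areas, centers, widths
#' free) used to recover exciton component positions from band-summed
#' spectral scans.
#'
#' @param wavelengths Wavelength grid (nm), e.g. spectral-scan band centers.
#' @param values Measured intensities.
#' @param init_centers Starting centers, one per component.
#' @param init_fwhm Starting FWHMs (recycled).
#' @param weights Optional fit weights (e.g. inverse shot-noise variances of
#'   band sums); default unweighted.
#' @return `data.frame` with one row per component: `center`, `fwhm`, `area`,
#'   sorted by center.
#' @export
fit_spectral_components <- function(wavelengths, values,
                                    init_centers = c(590, 620, 655),
                                    init_fwhm = 35, weights = NULL) {
  k <- length(init_centers)
  init_fwhm <- rep_len(init_fwhm, k)
  scale <- max(abs(values))
  if (scale <= 0) stop("spectrum is identically zero", call. = FALSE)
  y <- values / scale
  sig0 <- init_fwhm / (2 * sqrt(2 * log(2)))
  gauss <- function(x, a, m, s) a / (s * sqrt(2 * pi)) * exp(-(x - m)^2 / (2 * s^2))
  ## sequential peeling for the starting point: fit components one at a time
  ## on the residual, dominant (reddest) first, so weak blue components are
  ## initialized on what is left after the strong ones are explained
  ord <- order(init_centers, decreasing = TRUE)
  a0 <- m0 <- s0 <- numeric(k)
  resid <- y
  for (j in ord) {
    aj <- max(stats::approx(wavelengths, resid, xout = init_centers[j],
                            rule = 2)$y, 1e-9) * sig0[j] * sqrt(2 * pi)
    one <- tryCatch(
      minpack.lm::nlsLM(r ~ gauss(x, a, m, s),
                        data = data.frame(x = wavelengths, r = resid),
                        start = list(a = aj, m = init_centers[j], s = sig0[j]),
                        lower = c(0, init_centers[j] - 20, 2),
                        upper = c(Inf, init_centers[j] + 20, 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    p <- if (is.null(one)) c(a = aj, m = init_centers[j], s = sig0[j])
         else stats::coef(one)
    a0[j] <- p["a"]; m0[j] <- p["m"]; s0[j] <- p["s"]
    resid <- resid - gauss(wavelengths, a0[j], m0[j], s0[j])
  }
  ## joint refinement
  terms <- paste0("a", seq_len(k), "/(s", seq_len(k), "*sqrt(2*pi))*",
                  "exp(-(x-m", seq_len(k), ")^2/(2*s", seq_len(k), "^2))")
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  start <- c(stats::setNames(as.list(pmax(a0, 1e-9)), paste0("a", seq_len(k))),
             stats::setNames(as.list(m0), paste0("m", seq_len(k))),
             stats::setNames(as.list(pmax(s0, 2)), paste0("s", seq_len(k))))
  lo <- c(rep(0, k), init_centers - 25, rep(2, k))
  hi <- c(rep(Inf, k), init_centers + 25, rep(60, k))
  w <- if (is.null(weights)) rep(1, length(y)) else weights / mean(weights)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(x = wavelengths, y = y),
                      start = start, lower = lo, upper = hi, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- stats::coef(fit)
    a0 <- p[paste0("a", seq_len(k))]
    m0 <- p[paste0("m", seq_len(k))]
    s0 <- p[paste0("s", seq_len(k))]
  }
  out <- data.frame(center = unname(m0),
                    fwhm = unname(s0) * 2 * sqrt(2 * log(2)),
                    area = unname(a0) * scale)
  out[order(out$center), , drop = FALSE]
}
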