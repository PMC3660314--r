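---
title: "Tri-exciton confocal imaging in silico: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-exciton confocal imaging in silico: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdti)
```

# The physical picture

Quantum dots such as QD655 can absorb several photons in sequence under
continuous-wave illumination. With one electron-hole pair present the dot
emits around 655 nm (mono-exciton, MX); with two pairs the emission
blue-shifts to about 620 nm (bi-exciton, BX); with three pairs it shifts to
about 590 nm (tri-exciton, TX). Because generating an n-exciton state
requires n absorption events, its population scales with the *n-th power*
of the local excitation intensity before saturation. Detecting only the
blue-shifted tri-exciton band on an ordinary confocal microscope therefore
images an effective excitation distribution proportional to
$\mathrm{PSF}_{\mathrm{exc}}^3$, whose lateral width is the single-photon
width divided by $\sqrt{3} \approx 1.73$ for a Gaussian focus. That is the
entire resolution trick: no pulsed lasers, no switching buffers, just a
quantum dot, a violet laser, and a narrower detection band.

This package reproduces that imaging chain end to end in simulation, so the
resolution claims can be examined quantitatively: PSF models, QD
photophysics, synthetic specimens, image formation with noise, wavelength-
correct maximum-likelihood deconvolution, spectral unmixing, and FWHM-based
resolution metrics.

# PSF models

Two theoretical PSF models are provided; every PSF records which one built
it in its metadata.

**Gaussian model** (closed form, used throughout the tests): lateral FWHM
$0.51\,\lambda/\mathrm{NA}$ and axial FWHM
$0.88\,\lambda / (n - \sqrt{n^2 - \mathrm{NA}^2})$ with $n$ the immersion
index. The closed form makes the $\sqrt{n}$ narrowing of the n-th power
exact, which gives the test suite an analytic oracle.

**Paraxial scalar-diffraction model**: the scalar Debye integral
$h(r, z) = \int_0^1 J_0(k\,\mathrm{NA}\,r\rho)\,
e^{-i k\,\mathrm{NA}^2 z \rho^2 / 2n}\,\rho\,d\rho$, evaluated by Simpson
quadrature over the pupil. Its lateral width agrees with the Gaussian model
within a few percent at NA 1.4; its *axial* width is noticeably larger
because the paraxial approximation overestimates the axial extent at high
NA, whereas the Gaussian formula carries the high-NA correction. Only
lateral agreement is asserted as an invariant. Vectorial high-NA models and
index-mismatch aberrations are out of scope.

**Confocal detection.** One Airy unit is the Airy-disk diameter
$1.22\lambda_{em}/\mathrm{NA}$. The detection PSF is the emission-wavelength
PSF convolved slice-by-slice with an anti-aliased uniform disk of the
pinhole diameter (0.7 AU by default); no axial pinhole effect is modeled
beyond what the excitation-detection product provides.

**n-exciton PSF.** `make_nexciton_psf()` returns the normalized product
$\mathrm{PSF}_{\mathrm{exc}}^{\,n} \times \mathrm{PSF}_{\mathrm{det}}
(\lambda_{em}(n))$. Default emission wavelengths per order are 655, 620 and
580 nm. Note the asymmetry with the spectral model: spectrally the TX
component is centred at 590 nm, but the PSF for tri-exciton *imaging* is
evaluated at 580 nm, the blue edge of the 580-610 nm detection band used in
practice; both are configurable.

Grid conventions: voxel centers, center voxel at `floor(shape/2)` (0-based),
odd shapes enforced so a center voxel exists. FWHMs are measured on
through-center profiles by linear interpolation at half maximum; a
Gaussian-fit variant lives in the metrics module. Nyquist-compliant voxel
sizes are FWHM/2.3 per axis (the deconvolution community's usual factor;
configurable).

# Photophysics

`exciton_model()` describes emission as Gaussian spectral components tied to
exciton orders. The component weight at relative excitation intensity $I$ is

$$w_c(I) = y_c \left( \frac{I}{I + I_{sat}} \right)^{n_c},$$

a saturating power law: below saturation the TX/BX/MX signals scale as
$I^3 / I^2 / I^1$ (the property tests recover the exponents to 0.05), while
staying bounded at high power. Defaults that are *assumptions rather than
measured values*, and therefore exposed as parameters:

* spectral FWHMs 30/35/40 nm for MX/BX/TX (typical QD655 linewidths);
* relative yields 1 : 0.15 : 0.05 at saturation — a calibration knob chosen
  so the blue shoulder emerges between "low" and "high" laser settings;
* $I_{sat} = 1$ relative unit, with laser percentages mapping linearly as
  100% = 10 units (so typical tri-exciton settings of 20-40% sit at 2-4
  units, well into the nonlinear regime);
* the BX:TX photon ratio inside the 580-610 nm detection band follows from
  these choices but is physically unknown; the band integrals of the two
  components are reported separately so it can be inspected or recalibrated.

Because the TX yield is a small fraction of MX, the *summed* high-power
spectrum rises monotonically from 590 nm toward the BX/MX peaks rather than
showing a separate local maximum at 590 nm; the TX position is recovered by
fitting the three-component model (`fit_spectral_components()`, sequential
peeling initialization plus joint Levenberg-Marquardt refinement, optional
inverse-variance weights), not by peak picking.

Organic fluorophores (DAPI, Atto488, Alexa700) use the same machinery with
a single order-1 component and Gaussian excitation spectra; QD655 carries a
tabulated excitation-efficiency curve, monotonically decreasing from 405 to
650 nm — an analytic approximation shipped as package data, not a digitized
measurement. Cross-excitation in multiplexing scans follows from these
curves rather than from hard-coded bleed factors.

# Phantoms

Phantoms are defined in continuous nm coordinates and rendered onto the
voxel grid with sub-voxel accuracy:

* **Filaments** (25 nm diameter by default, microtubule-like) are polylines
  rendered as Gaussian line splats. The cross-section sigma combines the
  physical width (FWHM = diameter) with a **half-voxel anti-aliasing
  width** in quadrature; each filament's deposited total is then rescaled
  to exactly `emitters_per_um x length`, so the label total is conserved by
  construction and is orientation-independent (the residual grid aliasing
  of the unscaled splat is below 1%). The `parallel` layout used for
  resolution studies alternates filaments between two z-planes 1.5 um
  apart, so cross profiles of one filament are never contaminated by its
  lateral neighbors.
* **Vesicles**: solid spheres with diameters drawn from 50-250 nm, and
  hollow 0.7-0.9 um shells labeled only at the periphery, rendered as
  smoothed radial indicators with totals pinned to the analytic
  volume/surface times the labeling density. Antibody labeling densities
  are not well-constrained quantities; they are exposed as per-um^3 / per-um^2
  parameters with defaults chosen to land in a realistic 12-bit count range
  after the brightness calibration step below.
* **Test pattern**: a deterministic blob chart (size series, pair probes at
  configurable spacings, a substructure probe) for qualitative PSF
  demonstrations.

Ground-truth geometry is recorded exactly and round-trips through JSON at
full precision.

# Image formation

For each phantom label, the expected photon image is emitter density times
the label's absolute band signal — excitation efficiency at the laser line
feeding the saturating power law, emission spectrum integrated over the
detection band — summed over labels and convolved (FFT, reflective padding)
with the channel's n-exciton PSF. The detector applies Poisson statistics
at the quantum efficiency, linear gain, offset, Gaussian read noise, and
clipping to the 12-bit range; variance/mean of the offset-corrected counts
equals the gain (photon-transfer property, tested).

Spectral scans render one image per contiguous band, sharing the channel's
PSF across bands, which makes band additivity exact and lets a scan be
computed as one blur per label plus per-band scalings.

`plan_multiplex()` encodes the three supported two-scan multiplexing
schemes (organics first, then the high-power QDTX scan, which minimizes
bleaching of the organics; QDTX excitation moves to 488 nm when DAPI is
present and a 430-610 nm spectral scan plus unmixing is required when all
four labels are present). Channels listed within one scan are treated as
simultaneous — their detection bands are verified non-overlapping — since
that is what the non-overlapping band edges permit on real hardware; a
strictly sequential reading would not change any simulated result because
the channels are rendered independently. Bleaching is a stub flag only and
defaults to off.

Simulated brightness is calibrated the way a microscopist sets detector
range: a noiseless reference render fixes a scale factor so the channel of
interest peaks at a target count (200 counts for resolution studies,
~3000 counts — still inside 12 bits — for spectral component fitting).

# Restoration

`cmle_deconvolve()` implements Richardson-Lucy multiplicative updates for
the Poisson likelihood with a constant background term in the forward model
(`forward = est (*) PSF + b`), the algorithm family behind commercial
"CMLE" deconvolution. Convolutions inside the iteration are circular with a
unit-sum PSF, which makes two invariants exact and testable: the estimate
stays non-negative, and with zero background the total flux is conserved at
every iteration. The default is exactly 40 iterations. An optional
SNR-derived damping clips each update into $[1/c, c]$ with $c = 1 +
\mathrm{snr}$; background defaults to the mode of the intensity histogram.
The default protocol for tri-exciton images is the **order-2-model PSF at
the tri-exciton imaging wavelengths**: the detected band mixes BX and TX
photons, and the order-3 model is the aggressive choice that tends to
produce periodic background artifacts on real data. Both models run under
identical settings for comparison, and `periodicity_score()` quantifies the
artifact: the radially averaged power spectrum of the masked background,
averaged in equal-count frequency bins (so every bin has comparable
sampling noise), strongest bin over median bin. White noise scores near 1;
the suite's Monte-Carlo null stays below 3, while a planted 10% sinusoid
scores far above it. Whether our RL reproduces the specific commercial
failure mode is deliberately left unasserted — the comparison harness
exists, the verdict does not.

`linear_unmix()` solves per-voxel non-negative least squares against
band-integrated reference signatures (fast unconstrained solve for all
voxels, NNLS refinement only where negativity appears), returns one
abundance map per reference plus a residual map, and rejects rank-deficient
signature sets naming the most collinear pair. Noiseless unmixing is exact
to numerical precision (tested at 1e-6).

# Metrics

Line profiles are sampled by trilinear interpolation at voxel-size spacing
with in-plane width averaging. Two FWHM estimators are provided:
`interpolated` (half-maximum crossings above a local baseline, the outer
15% of samples — preferred for clean PSF profiles) and `gaussian_fit`
(Gaussian plus constant, the default for noisy data); both are invariant to
baseline offset and intensity scale and agree within 3% on clean Gaussians.
Whether experimental FWHMs should be baseline-corrected is ambiguous in
practice, so both estimators handle the baseline explicitly and record the
method used. `measure_filament_fwhms()` snaps profile endpoints to the
voxel lattice (axis-aligned profiles then sample voxel centers exactly,
avoiding interpolation broadening) and averages several cross-sections per
filament before fitting. `enhancement_report()` stores per-structure FWHMs
and recomputes fold ratios from them directly — no hidden state.

# Study designs and problem sizes

The two packaged experiments fix the study conditions:

* **Resolution-enhancement study** (`simulate_enhancement_study()`):
  12 straight 25 nm filaments in a 128 x 128 x 32 volume at 50 nm lateral /
  150 nm axial voxels (within the <= 60 nm pixel and 0.1-0.2 um z-step
  acquisition envelope), QD channel at 2% laser, QDTX at 30%, peak ~200
  counts, Poisson + read noise, 40 RL iterations. Gaussian-fit FWHMs per
  filament, means over n = 12.
* **Spectral study** (`simulate_spectral_study()`): 20 QD clusters
  (100-300 nm) in 128 x 128 x 24, 550-700 nm scan in 5 nm bands at 80%
  laser, peak ~3000 counts; brightness-weighted (matched-filter) cluster
  spectrum; three-component weighted fit. The weighting choices exist
  because the TX component carries only a few percent of the photons — an
  unweighted whole-volume sum is read-noise dominated and cannot pin a 3%
  component's center to a few nm.

These sizes run in seconds to a couple of minutes on a laptop core and are
the package's reference conditions; everything scales up by passing larger
`dim`.

# What the synthetic data does and does not show

The generator emulates geometry (filament packing, vesicle size ranges,
peripheral shell labeling), multi-exciton spectra with intensity-dependent
populations, cross-excitation, and shot/read noise. It does **not** emulate
spherical aberration, depth-dependent scattering, refractive-index
mismatch, QD blinking, or bleaching kinetics. Consequently the absolute
FWHMs measured on real specimens (a microtubule imaged in a conventional
QD channel comes out near 0.26 um on the bench) are *not* reproduced — our aberration-free
confocal PSFs are narrower than real ones — and the package's claims are
deliberately relative: fold reductions between channels measured on the
same structures, power-law exponents, spectral component positions, shell
interiors appearing after deconvolution. Passing tests therefore validate
the model chain and the relative enhancement mechanism, not absolute
instrument performance on tissue.

# Numerical choices and degenerate inputs

* PSF grids must be odd-sized; FWHM measurement errors out if the peak sits
  on a profile boundary or fewer than 5 samples exist.
* Multi-peak or flat profiles are rejected by the FWHM estimators
  (prominence check with a valley criterion) rather than silently fitted.
* RL with a delta PSF returns the background-subtracted input to 1e-9;
  all-zero images return zeros with a warning.
* Band integration interpolates the spectrum at band edges, making adjacent
  bands exactly additive.
* The emission grid default is 430-750 nm at 1 nm; image formation uses a
  wider 380-780 nm grid internally so violet detection bands (DAPI,
  415-470 nm) integrate correctly.
* Immersion/embedding refractive indices are rarely stated for typical
  acquisitions; the default is oil (1.515), flagged in the configuration,
  and the embedding medium is not modeled separately.
* Seeds: every stochastic entry point takes an explicit seed; the packaged
  studies derive their internal sub-seeds from it reproducibly.
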