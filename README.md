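# qdti — quantum-dot tri-exciton imaging, simulated and restored

Quantum dots like QD655 can absorb three photons in sequence under ordinary
continuous-wave illumination. The resulting tri-exciton (TX) state emits
blue-shifted light (~590 nm) that can be separated spectrally from the
mono- (MX, ~655 nm) and bi-exciton (BX, ~620 nm) emission. Because the TX
population scales with the **third power** of the excitation intensity, an
image formed from the TX band alone sees an effective PSF

    PSF_TX(r) ∝ PSF_exc(r)^3 · PSF_det(r; λ_TX),

whose lateral FWHM is the single-photon value divided by √3 ≈ 1.7 for a
Gaussian focus — sub-diffraction resolution on a completely standard
confocal microscope. Combined with maximum-likelihood deconvolution and
careful multi-color planning, this is a practical route to ~1.4–1.9-fold
resolution gains on cellular structures.

`qdti` is an R package for anyone who wants to study, teach, or extend that
imaging mode quantitatively without a microscope: it simulates the whole
chain (PSFs → QD photophysics → specimen phantoms → confocal acquisition
with noise → deconvolution/unmixing → FWHM metrics) and ships the analysis
tools one would apply to real stacks.

## What's inside

| Area | Functions |
| --- | --- |
| n-exciton confocal PSFs (Gaussian + scalar-diffraction models) | `optical_config()`, `make_excitation_psf()`, `make_detection_psf()`, `make_nexciton_psf()`, `psf_fwhm()`, `nyquist_sampling()`, `airy_unit_diameter()` |
| QD photophysics & spectra | `exciton_model()`, `exciton_weights()`, `emission_spectrum()`, `band_integrate()`, `fit_spectral_components()`, `fluorophore_panel()` |
| Seeded phantoms | `make_filaments()`, `make_vesicles()`, `make_test_pattern()`, `phantom_geometry()` |
| Image formation | `render_channel()`, `spectral_scan()`, `plan_multiplex()`, `simulate_plan()`, `detector_model()` |
| Restoration | `cmle_deconvolve()` (Richardson–Lucy with background), `linear_unmix()`, `periodicity_score()` |
| Metrics & I/O | `extract_line_profile()`, `estimate_fwhm()`, `measure_filament_fwhms()`, `enhancement_report()`, TIFF/YAML/CSV/JSON readers and writers |
| Packaged experiments | `simulate_enhancement_study()`, `simulate_spectral_study()` |

A thin command-line front end (`inst/cli/qdti.R`) exposes
`plan`, `simulate`, `deconvolve` and `measure` subcommands.

## Worked example

Simulate the microtubule-style resolution experiment: a seeded phantom of
25 nm filaments imaged in the conventional QD channel and the tri-exciton
channel, then deconvolved (order-2-model PSF at the tri-exciton
wavelengths, 40 Richardson–Lucy iterations):

```r
library(qdti)
study <- simulate_enhancement_study(seed = 1)
study$report
#> <enhancement_report> n = 12 structures
#>   QD -> QDTX:        1.50-fold (sd 0.06)
#>   QD -> QDTX decon:  3.03-fold (sd 0.13)
head(study$fwhm, 3)
#>         qd      qdtx    decon
#> 1 152.0767 102.87217 49.97784
#> 2 154.3788 100.91349 47.72228
#> 3 151.2130  99.78316 50.66957
```

Reading: each row is one filament; the conventional channel measures it at
~150 nm FWHM (aberration-free confocal at 405/655 nm), the tri-exciton
channel at ~100 nm (≈ 1.5-fold narrower), and the deconvolved tri-exciton
image at ~50 nm (≈ 3-fold). The fold ratios — not the absolute widths,
which on real, aberrated samples are larger — are the quantity of interest.

The spectral side: a high-power 550–700 nm spectral scan of QD clusters,
with a three-component fit recovering the tri-exciton center:

```r
spec <- simulate_spectral_study(seed = 1)
spec$fit
#>     center     fwhm      area
#> 1 589.8054 40.04336  1176.503
#> 2 619.8536 34.93892  3957.821
#> 3 654.9722 30.23170 29873.510
spec$tx_center
#> [1] 589.8054
```

The bluest component lands at ~590 nm — the tri-exciton emission — with the
bi- and mono-exciton components at 620 and 655 nm.

Multiplexing plans mirror the standard acquisition schemes:

```r
plan_multiplex(c("DAPI", "QD655", "Alexa700"))
#> <scan_plan> Alexa700 + DAPI + QD655
#>   Scan 1:
#>     DAPI     Ex405/Em415-470
#>     Alexa700 Ex633/Em700-750
#>   Scan 2:
#>     QD655    Ex488/Em560-610
```

(QDTX excitation moves to 488 nm here precisely because 405 nm would
cross-excite DAPI.)

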