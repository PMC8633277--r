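# nanosnom

Infrared near-field nanoscopy below the diffraction limit: an R toolkit
that simulates and analyses the full computational chain of
scattering-type scanning near-field optical microscopy (sSNOM) and
nanoFTIR spectroscopy of resin-embedded cellular cross sections — from
dielectric cell phantoms, through tip-scattering demodulation and
interferogram-based spectral retrieval, to single-wavenumber chemical
imaging and serial-section tomographic reconstruction.

It is written for microscopists and method developers who want a
ground-truth testbed for sSNOM/nanoFTIR analysis: every operation the
instrument chain performs (pseudoheterodyne sideband extraction, FFT
retrieval, gold referencing, profile measurement, section registration)
is implemented against synthetic phantoms whose geometry and chemistry
are known exactly.

## The model in brief

* **Materials.** Compartments carry Lorentz-oscillator dielectric
  functions
  ε(ν) = ε∞ + Σⱼ Sⱼνⱼ²/(νⱼ² − ν² − iγⱼν),
  with bands at the standard mid-IR assignments: resin C=O 1738 cm⁻¹,
  amide I/II 1655/1540 cm⁻¹, phosphate 1238 cm⁻¹, carbohydrate
  1155 cm⁻¹; gold is a flat near-perfect reflector.
* **Tip.** Quasi-electrostatic point dipole with conducting spherical
  apex: α_eff = α(1+β)/(1 − αβ/16π(a+g)³), β = (ε−1)/(ε+1), tapped
  sinusoidally and demodulated at harmonic n of the tapping frequency
  (background-free for n ≥ 1).  Pseudoheterodyne detection recovers the
  complex signal from sidebands nΩ ± mM weighted by Bessel functions of
  the modulation depth.
* **Spectroscopy.** Interferograms on the mirror-travel axis, one-sided
  FFT retrieval (16 cm⁻¹ resolution, Hann apodization, 4× zero-fill),
  and the referenced near-field absorption
  **A(ν) = (sₙ/sₙ,ref) · sin(φₙ − φₙ,ref)** against a gold reference.
* **Imaging & tomography.** Raster scans with a harmonic-sharpened
  Gaussian point-spread function (FWHM 2a/√n); 10–90% edge widths, FWHM
  feature sizes and azimuthal peak counts from line profiles;
  phase-correlation registration (sub-pixel, upsampled 10×) of serial
  sections into anisotropic-voxel volumes.

## Worked example

```r
library(nanosnom)

pal  <- material_palette()
tip  <- tip_model()                      # 10 nm apex, 50 nm tapping
grid <- spectral_grid()                  # 16 cm^-1, 1000-1800 cm^-1

## nanoFTIR spectrum of the embedding resin, referenced against gold
gold <- gold_spectrum(tip, 2, grid)
ifg  <- synthesize_interferogram(pal$resin, tip, 2, grid)
A    <- near_field_absorption(spectrum_from_interferogram(ifg), gold)
find_peaks(A)[1, ]
#>   wavenumber     height
#> 1       1748 0.01758558

## image a cell section at amide I and measure the nuclear body
phantom <- build_cell_phantom(seed = 1)
stack   <- section_phantom(phantom, 100, 10)        # ten 100 nm sections
img     <- raster_scan(get_section(stack, 7), 1655, tip, 2,
                       pixel_pitch_nm = 20)
img
#> <scan_image> 128 x 128 px at 20 nm, nu = 1655 cm^-1, n = 2
```

The resin absorption peaks within one resolution element of its
1738 cm⁻¹ carbonyl band; the 1655 cm⁻¹ phase image shows protein-rich
compartments bright against dark resin (the contrast inverts at
1738 cm⁻¹), and a line profile across the phantom's 200 nm nuclear body
returns its diameter to within one pixel.  Registering the ten section
images and calling `assemble_tomogram(...)` yields a 1 µm-deep volume of
20 × 20 × 100 nm voxels; `voxel_volume_liters(c(20, 20, 1000))` gives the
4 × 10⁻¹⁹ L (400 zL) voxel of a full-thickness column.

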