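---
title: "Models and methods behind nanosnom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanosnom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosnom)
```

`nanosnom` simulates the computational chain of scattering-type scanning
near-field optical microscopy (sSNOM) and nanoFTIR spectroscopy applied to
resin-embedded cellular cross sections, and provides the analysis
operations — spectral peak assignment, profile-based feature measurement,
and serial-section tomography — that such data support.  Because the
physical instrument is not reproducible on a desk, every method is
exercised against *synthetic phantoms with known ground truth*: the
phantom generator is first-class, tested code, and every downstream claim
(band position, edge width, feature size, doublet count, registration
accuracy) is validated by recovering what was built in.

## Dielectric model

Each compartment material is a Lorentz-oscillator dielectric function

$$\varepsilon(\nu) = \varepsilon_\infty + \sum_j
  \frac{S_j\,\nu_j^2}{\nu_j^2 - \nu^2 - i\,\gamma_j\,\nu},$$

with band centers $\nu_j$ at the standard mid-IR assignments: embedding
resin carbonyl at 1738 cm⁻¹, protein amide I/II at 1655/1540 cm⁻¹,
nucleic-acid phosphate at 1238 cm⁻¹, carbohydrate C–O–C at 1155 cm⁻¹.
Only the band *positions* are anchored to published assignments;
oscillator strengths and linewidths of biological materials are not
tabulated anywhere at this specificity, so they are free parameters of the
model.  Defaults use $\gamma = 30$ cm⁻¹ (a typical condensed-phase mid-IR
linewidth) and strengths chosen so peak $\mathrm{Im}\,\varepsilon$ falls in
roughly 0.2–0.9, with amide I configured stronger than amide II.  The gold
reference surface is a fixed $\varepsilon = -5000 + 1000i$: in the mid-IR
gold is so close to a perfect reflector that a frequency-resolved Drude
fit would change the referenced contrast by less than the retrieval noise
floor, and a flat reference divides out of every referenced quantity.

The model is passive by construction ($\mathrm{Im}\,\varepsilon \ge 0$ for
all $\nu > 0$), asserted on a 1 cm⁻¹ grid over the 1000–1800 cm⁻¹ working
band for the whole palette.

## Tip–sample scattering and demodulation

The probe is a quasi-electrostatic point dipole with a perfectly
conducting spherical apex of radius $a$ (default 10 nm): bare
polarizability $\alpha = 4\pi a^3$, sample surface response
$\beta = (\varepsilon-1)/(\varepsilon+1)$, and gap-dependent dressed
polarizability

$$\alpha_{\mathrm{eff}}(g) = \frac{\alpha\,(1+\beta)}
  {1 - \alpha\beta / \left(16\pi (a+g)^3\right)}.$$

This is the simplest model whose limits are all analytically checkable
(vacuum, conductor, retracted tip), which is what the test suite leans on.
The finite-dipole model would change absolute contrast levels but not the
structure of the chain; it is a possible extension point, not a default.

The tip taps sinusoidally, $g(t) = g_{\min} + A(1 + \cos 2\pi\Omega t)$
(defaults $g_{\min} = 1$ nm, $A = 50$ nm), and the scattered field is
demodulated at harmonic $n$ of $\Omega$ with one-sided Fourier convention
$c_n = (2/N)\sum_k E(t_k)\,e^{-2\pi i n t_k}$.  Any gap-independent
far-field background is a constant over the cycle and contributes exactly
zero at $n \ge 1$ — the property that makes demodulation background-free,
tested to $10^{-10}$ relative.  All imaging and spectroscopy defaults use
$n = 2$, the lowest background-safe harmonic; the harmonic is
configurable and nothing in the chain depends on the choice beyond
signal-to-contrast ratios.

The phase sign convention is fixed so that an absorbing sample *leads* the
gold reference phase at band center, making the referenced absorption
(below) positive on resonance.

### Pseudoheterodyne detection

In imaging mode the reference arm is phase-modulated,
$E_{\mathrm{ref}}(t) = \rho\,e^{i\gamma_m \sin 2\pi M t}$, and the detector
intensity $|E_s + E_{\mathrm{ref}}|^2$ carries the complex near-field
harmonics in sidebands at $n\Omega \pm mM$.  Writing
$E_s(t) = \sum_n a_n \cos 2\pi n\Omega t$ and expanding the modulation in
Bessel functions, the upper-sideband coefficients are
$(\rho J_m(\gamma_m)/2)\,\big((-1)^m a_n + a_n^*\big)$, so

$$\mathrm{Re}\,a_n = \frac{u_{n,2}}{2\rho J_2}, \qquad
  \mathrm{Im}\,a_n = \frac{i\,u_{n,1}}{2\rho J_1}.$$

The package uses $M/\Omega = 1/16$ exactly and samples one full common
period, so every sideband falls on an exact frequency bin and the
extraction is leakage-free; real instruments use incommensurate
frequencies, which matters for hardware lock-ins but not for a sampled
simulation.  The default modulation depth is 2.63 rad; any depth away from
the Bessel zeros works and the extraction refuses depths within $10^{-3}$
of a zero.  A complex calibration factor determined once on gold absorbs
the residual fixed phase/scale, after which sideband extraction agrees
with direct harmonic demodulation to better than $10^{-6}$ relative — an
identity the suite checks over 20 seeded material/wavenumber draws.

## nanoFTIR retrieval and referenced absorption

The broadband chain synthesizes the asymmetric-interferometer record from
the per-wavenumber demodulated response times a Gaussian source envelope
(center 1400 cm⁻¹, FWHM 700 cm⁻¹ — the exact shape divides out under
referencing, it only needs to cover the band).  The stored axis is the
reference-mirror displacement $x$; the beam double-passes the reference
arm, so the optical path difference is $2x$ and the spectral resolution is
$\Delta\nu = 1/(2 x_{\max})$.  The default $x_{\max} = 312.5$ µm gives
$\Delta\nu = 16$ cm⁻¹ with a native FFT bin spacing equal to
$\Delta\nu$, 400 samples per record, and a 3200 cm⁻¹ Nyquist limit.

Retrieval is a one-sided FFT of the real record with apodization and
$4\times$ zero-filling, keeping the complex spectrum (no Mertz phase
correction — the simulated spectrum is intrinsically complex and the phase
is signal, not error).  The default window is a one-sided Hann
($\cos^2$, unity at zero path difference).  This choice was made on
resolution grounds: stronger windows (three-term Blackman–Harris is
available) widen the instrumental line to ~2 bins, which merges lines
separated by one resolution element and biases band-peak positions by up
to a resolution element; the boxcar resolves but its 22% sidelobes
produce spurious local maxima in referenced spectra.  Hann resolves two
synthetic lines 16 cm⁻¹ apart exactly at their positions and keeps every
palette band top within one resolution element of its oscillator center.

Near-field absorption is the referenced quantity

$$A(\nu) = \frac{s_n(\nu)}{s_{n,\mathrm{ref}}(\nu)}
  \sin\!\big(\varphi_n(\nu) - \varphi_{n,\mathrm{ref}}(\nu)\big),$$

with gold as reference and the phase difference wrapped to $(-\pi, \pi]$
before the sine so the formula is total rather than small-angle.
Self-referencing gives identically zero; halving all oscillator strengths
halves peak $A$ to within 15% (weak-scatterer linearity).

## Phantoms: what the synthetic data emulate

`build_cell_phantom()` constructs a 3-D labeled voxel grid (10 nm pitch,
$(z, y, x)$ order, pixel centers at half-integers) of a resin-embedded
eukaryotic cell: resin background, an 80 nm cell-wall shell, cytoplasm
modelled as resin-penetrated ground mass (its spectra mix the carbonyl
and weak amide bands, as cytoplasmic regions of embedded cells do),
nucleus with nucleolus and one 200 nm spherical nuclear body, a pyrenoid
wrapped in starch plates with azimuthal gaps, thylakoid lamellae clipped
to the cell interior, and seeded resin-filled vacuoles.
`build_axoneme_phantom()` builds the canonical 9+2 flagellar cross
section: nine overlapping-tubule doublets (doublet 1 at azimuth 0 by
convention), radial spokes, central pair, inner sheath, membrane ring.

The default cell diameter is 2 µm on a 2.56 µm grid — the package's
desk-scale working size; all geometry is configurable through
`cell_geometry()`, and every downstream measurement reads positions from
the build provenance rather than assuming them.  What the phantoms do
*not* emulate: real ultrastructural texture, membrane substructure,
staining-density variation, topographic roughness, or subsurface response.
Passing tests therefore demonstrate that the *computational chain* is
correct and self-consistent — they do not validate the point-dipole model
against a physical instrument.

`section_phantom()` slices the phantom into consecutive slabs (default
100 nm, ten sections = 1 µm), projecting each slab to a 2-D label map by
per-column majority vote with ties broken toward the lowest label code —
a deterministic, testable stand-in for what a microtomed section presents
to the tip.  Misalignment jitter (translations quantized to the in-plane
voxel grid so the recorded ground truth is exactly realizable, plus small
rotations) emulates ribbon placement; section 1 is never jittered and a
zero-jitter configuration gives exactly zero offsets.

## Imaging model

`raster_scan()` paints the per-material complex demodulated response onto
the section, applies a lateral Gaussian point-spread kernel, and samples
the blurred *complex field* at the pixel pitch (default 20 nm); amplitude
and phase are taken after blurring, so material boundaries mix coherently
as they do under a real tip.  The kernel FWHM is
$2a/\sqrt{n}$: demodulation at harmonic $n$ weights the $n$-th power of
the sharply gap-dependent near field, which for a Gaussian confinement
narrows the effective spot by $\sqrt{n}$.  At the defaults (10 nm apex,
$n = 2$) the 10–90% width of a phase edge across a resin/protein boundary
is ≈ 18 nm, consistent with the ~20 nm lateral resolution that sSNOM
reports with tips of this size, and resolution degrades monotonically
with apex radius.  Topography is a configured per-material relief
(default +2 nm for cellular material) smoothed with the same kernel — a
co-registered context channel, not a contact-mechanics simulation.

Measurements are profile-based, as in practice: `edge_width_10_90()` uses
the 10–90% criterion (the common near-field convention; the criterion is
reported with the number), requiring a monotone edge; `feature_fwhm()`
measures full width at half maximum above a local baseline taken as the
median of the profile ends — which is why the built-in measurement paths
choose profiles whose ends rest on a single surrounding material;
`count_azimuthal_peaks()` unwraps an annulus at 1° sampling and counts
circular local maxima above the annulus median, merging maxima closer
than half the expected period when a period hint is given.

## Tomography

Serial sections are registered by phase correlation: whitened cross-power
for the coarse integer peak, then sub-pixel refinement by upsampled
(factor 10) cross-correlation in a small neighborhood, with an optional
coarse rotation search (±3° in 0.25° steps).  Pairwise transforms are
chained to the frame of section 1 — ribbon sectioning keeps inter-slice
offsets small, and drift accumulation is tested explicitly rather than
bundle-adjusted away.  Low-confidence pairs (e.g. a blank slice) are
flagged and contribute an identity increment instead of failing the run.
On a z-uniform phantom with seeded jitter the recovered offsets match the
ground truth with RMS error below 0.25 px, including half-pixel offsets.

`assemble_tomogram()` resamples each slice under its transform (bilinear;
out-of-frame voxels are NA and excluded from statistics) and stacks them
with anisotropic voxel metadata $(p, p, d_z)$; ten 100 nm sections at
20 nm pitch give a 1 µm volume.  No z-interpolation is performed — the
voxel *is* the slab.  `voxel_volume_liters()` converts voxel dimensions
exactly (1 nm³ = 10⁻²⁴ L): a 20 × 20 × 1000 nm voxel is
4 × 10⁻¹⁹ L = 400 zL.

## Numerical choices and degenerate inputs

* All randomness flows through explicit per-build seeds (`with_seed`
  restores the caller's RNG state); noiseless paths are bitwise
  deterministic.
* Phases are always wrapped to $(-\pi, \pi]$.
* The dipole denominator, the $\varepsilon = -1$ surface-response pole,
  zero reference amplitudes (reported with the offending bins), Bessel-zero
  modulation depths, non-monotone edges, featureless profiles and blank
  registration slices all raise informative errors rather than returning
  numbers.
* Problem sizes used by the test suite and the reproduction script: a
  2 µm cell on a 256 × 256 × 130 voxel grid, 400-sample interferograms,
  128 × 128 px scans, ten-section stacks — sizes at which the full suite
  runs in well under a minute of compute per module.

## Known limitations

The point-dipole model has no retardation, antenna or multilayer
subsurface response; topography is schematic; the interferogram model has
no detector nonlinearity or water-vapor lines; registration assumes rigid
in-plane motion; and no optical-constant inversion (Kramers–Kronig or
otherwise) is attempted from $A(\nu)$.  Chained registration across
*changing* section content carries a content-difference bias that the
z-uniform recovery tests deliberately exclude; the assembly test bounds
its effect instead (mean absolute error under 10% of dynamic range).
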