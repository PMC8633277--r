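Package: nanosnom
Title: Simulation and Analysis of Infrared Near-Field Nanoscopy and
    Serial-Section Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing scattering-type scanning
    near-field optical microscopy (sSNOM) and nanoFTIR spectroscopy of
    resin-embedded cellular cross sections.  Provides Lorentz-oscillator
    dielectric models of biomolecular infrared bands, synthetic labeled
    cell and axoneme phantoms with serial sectioning, a point-dipole
    tip-scattering model with harmonic and pseudoheterodyne sideband
    demodulation, interferogram synthesis and Fourier-transform spectral
    retrieval with gold-referenced near-field absorption, single-wavenumber
    amplitude and phase raster imaging with profile-based feature
    measurements, and phase-correlation registration of serial sections
    into anisotropic-voxel tomographic volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    tools,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
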