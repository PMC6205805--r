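Package: darkfieldsim
Title: Wave-Optics Simulation of Grating-Interferometry X-Ray Dark-Field Lung Radiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monochromatic wave-optics simulator of Talbot grating interferometry
    for x-ray dark-field (DF) radiography of lung tissue. The lung is modelled as a
    slab of muscle tissue filled with randomly placed, overlapping air spheres
    (alveoli); the complex wavefield is propagated through the object and the
    phase grating to the analyzer grating by Fresnel (angular-spectrum)
    propagation, phase-stepping frames are formed with a configurable detector
    model (pixel binning, exposure scaling, MTF/focal-spot blur, NPS-shaped
    noise), and transmission, differential-phase and dark-field images are
    retrieved by Fourier analysis of the stepping curve. Thickness series of the
    field-of-view mean dark-field signal are fitted to estimate the material
    linear diffusion coefficient epsilon, with presets for murine and human
    lung imaging geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
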