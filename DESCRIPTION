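Package: diattsim
Title: Simulation and Analysis for Diattenuation Imaging of Nerve Fibre Tissue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling and analysing diattenuation imaging (DI) of
    myelinated nerve fibre tissue. Generates dense, collision-free synthetic
    fibre bundles with controlled orientation dispersion and inclination,
    voxelizes them into layered axon/myelin/glycerine refractive-index volumes,
    propagates linearly polarised monochromatic plane waves through the volumes
    with a finite-difference time-domain (FDTD) Maxwell solver on a Yee grid,
    and images the exit field through a virtual polarising microscope (numerical
    aperture filter and microlens averaging) to obtain scattering-diattenuation
    maps. Includes the closed-form retardation and dichroism models, a forward
    generator for rotating-polariser intensity series, and the measurement-side
    harmonic Fourier analysis that turns such series into direction, phase,
    and diattenuation-strength maps with D+/D- classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Rcpp (>= 1.0.0),
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Visualization, BiomedicalInformatics
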