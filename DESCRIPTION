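Package: solls
Title: Simulation and Analysis of Single-Objective Lattice Light Sheets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scalar Fourier-optics simulation of single-objective lattice and
    Gaussian light sheets generated by a back-focal-plane slit photomask and
    redirected by a micromirror, together with the quantification and
    single-molecule analysis tools used to characterize them. Includes
    angular-spectrum free-space propagation, ideal-lens Fourier mapping, beam
    dithering/steering/reflection, split-step propagation through random
    scattering media, beam metrics (1/e2 thickness curves and the sqrt(2)
    effective-range criterion), a synthetic single-molecule movie generator
    with double-helix point spread functions and EMCCD noise, and a
    localization pipeline (wavelet spot detection, weighted least-squares
    Gaussian fitting, EMCCD localization precision, double-helix z fitting,
    fiducial drift correction, filtering, axial rescaling, region statistics,
    signal-to-background ratios, and Fourier ring correlation resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
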