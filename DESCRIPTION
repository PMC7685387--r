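Package: aoldv
Title: Absolute Retinal Blood Flow from Adaptive-Optics Laser Doppler
    Velocimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computational pipeline of an adaptive-optics bidirectional laser
    Doppler velocimeter for absolute retinal blood flow: Doppler power spectra
    from two-channel detector records, cutoff-frequency estimation by the
    cumulative-spectrum two-line intersection method, absolute maximum
    red-blood-cell velocity from the bidirectional scattering geometry, vessel
    lumen diameter from 16-bit adaptive-optics fundus images with
    pixel-to-micrometer calibration, Poiseuille flow computation, and
    flow-conservation analysis at venous bifurcations. Includes a
    physics-grounded simulator (step-shaped laminar Doppler spectra, capillary
    spectra with centre-weighted beam illumination, fundus vessel phantoms,
    full bifurcation scenarios) so that every pipeline stage can be validated
    against ground truth without the instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
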