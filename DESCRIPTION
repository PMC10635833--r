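Package: condensateR
Title: Mechanics and Dynamics of Biomolecular Condensates from Optical
    Trapping, FRAP and Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying the material state of
    protein condensates and their liquid-to-solid transition. Converts
    dual-optical-trap force recordings on single droplets into
    frequency-resolved complex shear moduli and Maxwell-model parameters
    (plateau modulus, dashpot viscosity, crossover frequency), fits
    fluorescence recovery after photobleaching (FRAP) curves for mobile
    fraction and Soumpasis diffusion coefficients, computes mean squared
    displacement and mobility classification from particle tracks,
    derives FRET tension indices by linear unmixing of three-cube image
    stacks, and tests two-channel colocalization against a block-scramble
    permutation null. Every analysis stage is paired with a synthetic
    data generator with known ground truth so the whole chain is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite,
    tiff,
    EBImage,
    digest,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
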