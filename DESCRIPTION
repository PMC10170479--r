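Package: mucochip
Title: Analysis Toolkit for Airway Epithelium-on-Chip Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of airway epithelium-on-chip readouts:
    multiple-particle-tracking microrheology of mucus (spot detection,
    proximity-principle trajectory linking, mean-squared-displacement
    estimation and viscosity/elastic-modulus extraction via the generalized
    Stokes-Einstein relation), equivalent-circuit fitting of epithelial
    impedance spectra (TEER and capacitance time courses), a reduced-order
    laminar-flow and oxygen-transport solver for the microfluidic chip
    (wall shear stress, near-membrane velocity, Michaelis-Menten oxygen
    consumption), ciliary beat frequency extraction from high-frame-rate
    video, and fluorescence morphometry including mucus-layer thickness
    from two-channel confocal z-stacks. Synthetic-data generators with
    known ground truth accompany every stage so the whole pipeline is
    verifiable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
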