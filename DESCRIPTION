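Package: epidqa
Title: EPID-Based Daily Linac Quality Assurance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vendor-independent daily quality-assurance analysis of megavoltage
    portal images from a linac-mounted electronic portal imaging device (EPID).
    From one 10 cm x 10 cm open-field and one 60-degree-wedge acquisition the
    package computes output constancy (mean central-ROI signal), beam flatness
    and symmetry over the central 80 percent of the field, a wedge-factor
    beam-quality surrogate, field size and field centre located sub-pixel from
    profile-derivative extrema, and compares them against a stored yearly
    benchmark under TG-142-style tolerances. Readers for iViewGT-style 16-bit
    TIFF and DICOM RT Image exports, a physically plausible synthetic generator
    for flattened, flattening-filter-free and wedged beams with known ground
    truth, validation experiments (MU linearity, ROI shift sensitivity,
    collimator-pair radiation centre, adjacent-field-size steps), and a
    command-line front end for unattended morning checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
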