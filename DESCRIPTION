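Package: phantomADC
Title: Automated ADC Quality Assurance for Diffusion MRI Phantoms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Automated analysis of diffusion-weighted MRI of the
    NIST/NCI/RSNA 13-vial diffusion phantom. Reads classic DICOM series,
    normalises vendor-specific metadata, detects vial regions of interest
    by shape matching or rigid registration, estimates apparent diffusion
    coefficients (ADC) with a log-linearised mono-exponential model, maps
    spatial ADC bias in cylindrical vial coordinates, and computes QIBA
    diffusion-profile conformance metrics, repeatability and
    reproducibility coefficients, and TOST equivalence statistics.
    Includes a synthetic phantom-image generator so the full pipeline is
    testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
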