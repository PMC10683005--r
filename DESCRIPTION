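Package: cadlink
Title: Link Charged Aerosol Detector Peaks to LC-MS Features for
    Semiquantitative Metabolome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated composition assessment of natural extracts from
    multi-detector LC runs. Pretreats charged aerosol detector (CAD)
    chromatograms (detector-lag alignment, Fourier low-pass denoising,
    even-derivative peak sharpening, uniform resampling), detects and
    integrates CAD peaks, attributes untargeted LC-MS/MS features to CAD
    peaks by peak-shape correlation, classifies features into the major
    and minor metabolome through a peak-shape, taxonomic and
    annotation-confidence filter cascade, and produces semiquantitative
    reports, pseudochromatograms, treemap fractions and CAD-decorated
    molecular networks. Includes a seeded synthetic data generator that
    emulates multi-detector acquisitions with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
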