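Package: fluormargin
Title: Fluorescence-Guided Surgical Margin Assessment with 5-ALA-Induced
    PpIX Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for protoporphyrin IX (PpIX) fluorescence
    imaging of breast surgical specimens after oral 5-aminolevulinic acid
    (5-ALA). Provides synthetic specimen simulation (tissue label maps,
    spectrally rendered RGB fluorescence images, punch-biopsy sampling and
    point spectra), CIE 1931 chromaticity contrast analysis of tumor versus
    normal tissue, dominant-wavelength fluorescence color classification,
    stratified diagnostic accuracy statistics (PPV, NPV, sensitivity,
    specificity with Clopper-Pearson exact confidence intervals, and the
    diagnostic odds ratio with a log-scale normal-approximation interval),
    635 nm spectral peak detection, and biopsy tissue-composition analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    png,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
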