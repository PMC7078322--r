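Package: tdevtools
Title: Automated Enumeration of Tumour-Derived Extracellular Vesicles and
    Their Association with Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale emulation of automated tumour-derived
    extracellular vesicle (tdEV) enumeration from CellSearch-style
    multichannel fluorescence cartridge images, and of the downstream
    survival-association analyses. Provides a calibrated synthetic
    cartridge renderer with ground truth, full-detection style object
    segmentation and per-channel feature measurement, a declarative
    linear-gate engine with the canonical tdEV gates, a copula-based
    patient-cohort simulator with proportional-hazards survival,
    self-contained Kaplan-Meier, log-rank, Cox (including forward
    stepwise selection), rank-correlation, rank-sum and ROC procedures,
    and Cutoff-Finder-style hazard-ratio-versus-cutoff scans with
    favourable-CTC sub-stratification and healthy-donor reference
    ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
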