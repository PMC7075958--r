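Package: mhf
Title: Mutation Hotspot Finder for Protein Functional Domains
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bootstrap-resampling test for clustering of single amino acid
    disease variants within annotated protein functional domains, with an
    analytic binomial oracle, Bonferroni-corrected empirical p-values, exact
    2x2 association testing between hotspot membership and clinical severity,
    a synthetic-data simulation harness for type-I error and power
    calibration, and small electrophysiology analysis routines (Boltzmann
    activation fits, activation time constants, voltage-sensitive-phosphatase
    current decay). Developed around the KCNQ2/Kv7.2 epilepsy variant
    clustering problem but applicable to any protein with an interval domain
    annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
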