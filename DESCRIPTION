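Package: glycotyper
Title: Classification and Identification of Intact N- and O-Glycopeptides
    from HCD Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying intact glycopeptides in
    higher-energy collisional dissociation (HCD) tandem mass spectra.
    Detects oxonium-ion-containing MS/MS scans, extracts nine
    204-normalized oxonium intensity ratios and classifies each spectrum
    as N- or O-glycopeptide by logistic regression, and identifies
    glycopeptides by precursor-mass matching of tryptic peptides against
    glycan composition databases with a modified Morpheus score and
    shuffle-decoy false discovery rate control. Supports a conventional
    search of both glycan spaces and a faster pre-classification mode
    that searches only the predicted space. Includes a synthetic HCD
    glycopeptide spectrum generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
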