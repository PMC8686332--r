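Package: phaquant
Title: Profiling of PhaC Polymerases and Semi-Quantitative PHA Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for characterizing bacterial polyhydroxyalkanoate (PHA)
    producers. Computes physicochemical profiles of PhaC polymerase candidates
    (average molecular weight, segmented Bjellqvist isoelectric points, PhaC-box
    and AAKP motif scans, variant classification), the semi-quantitative C:A 1
    ratio from FT-IR spectra (carbonyl-ester over amide band I region areas,
    with baseline correction and carbonyl-peak detection), specific growth
    rates from OD600 time series, and PHA titer arithmetic from cell dry weight
    and monomer fractions. Includes seeded generators for synthetic proteins,
    spectra and growth curves with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
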