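Package: pepshift
Title: Peptide-Map Differential Analysis for pH-Shift-Treated Allergens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how protein processing treatments (such as
    pH-shift unfolding/refolding of peanut protein) change tryptic peptide
    maps and IgE-binding readouts. Provides in-silico trypsin digestion with
    missed cleavages and a detection-length window, label-free peptide
    relative-abundance classification against a control condition,
    inference of exposed or masked trypsin cleavage sites from differential
    peptide evidence, intactness reporting for linear IgE-binding epitopes,
    four-parameter-logistic fitting of competitive-ELISA inhibition curves
    with IC50 estimation, and a seeded synthetic-data generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
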