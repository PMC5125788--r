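Package: leptobarcode
Title: COI Barcode Identification Pipeline for Eel Leptocephali
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable implementation of the molecular identification
    workflow used for anguilliform leptocephali: functional-barcode quality
    control under the vertebrate mitochondrial code, similarity-based tiered
    taxonomic rank assignment (species/genus/family thresholds 98/92/85),
    neighbour-joining trees from uncorrected p-distances with column-resampling
    bootstrap, within/between group distance tables, single-position diagnostic
    character classification, and a barcode-gap MOTU congruence report.
    Includes a seedable synthetic COI reference-library generator with a
    hierarchical divergence structure so the entire pipeline can be exercised
    and tested offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
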