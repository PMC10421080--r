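Package: isopair
Title: Isotope-Tagged Peak-Pair Detection in LC-MS Feature Tables
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computational screening of stable-isotope-tagged natural-product
    extracts by LC-MS. Detects co-eluting light/heavy isotopologue peak pairs
    created by 1:1 12C3/13C3-propanoyl shotgun derivatization in aligned
    feature tables using ppm mass, retention-time, and intensity-similarity
    tolerances; performs tag and adduct mass arithmetic to infer untagged
    parent ions; and cross-references hit tables recorded before and after a
    live-cell affinity assay to nominate enriched, potentially bioactive
    compounds. Includes a seeded synthetic feature-table generator with full
    ground truth for end-to-end validation, CSV readers for MS-DIAL and
    generic feature-table dialects, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
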