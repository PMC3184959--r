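Package: pcfam
Title: Phytocyanin Gene Family Classification, Duplication and Expression
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of the plant phytocyanin (blue
    copper protein) gene family. Implements amino-acid bias and
    arabinogalactan-protein (AGP) glycomodule detection in Pro-rich regions,
    copper-ligand extraction from plastocyanin-like domains with
    uclacyanin-like / stellacyanin-like / early-nodulin-like subfamily
    assignment, six-type protein architecture classification (signal peptide,
    AGP-like region, GPI-anchor signal), tandem and segmental gene-duplication
    detection, digital expression rules for EST, MPSS and microarray data,
    qRT-PCR relative quantification by the standard-curve method, and a small
    neighbor-joining phylogeny with bootstrap support. Includes seeded
    synthetic-data generators that emit family fixtures with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
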