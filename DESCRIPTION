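Package: pals
Title: Peptide-Barcode Design and Quantitation for Pooled Lipid
    Nanoparticle Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proteomics-based pooled screening of lipid
    nanoparticles (LNPs) that deliver barcoded mRNA. Designs
    mass-spectrometry-resolvable peptide barcodes encoded at the 3' end of
    an open reading frame (core enumeration, residue and proline rules,
    MS1/MS2 resolvability filtering, isobaric library construction),
    verifies tryptic release of the barcodes by in-silico digestion,
    reverse-translates barcoded proteins into GC-targeted nucleotide
    sequence, converts per-animal per-barcode peak areas into normalized
    relative quantities and LNP rankings with exact signed-rank
    concordance statistics, and simulates pooled screens (Hill
    dose-response, inter-animal variability, measurement noise, LOQ
    censoring) for design and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
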