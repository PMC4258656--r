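Package: ampliscreen
Title: In Silico Auditing and Design of PCR Screening Assays for
    Promoter Variant Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit PCR screening assays (primer/probe sets)
    against panels of diverged target sequences, with the CaMV 35S
    promoter (P35S) used in GMO screening as the motivating system.
    Maps promoter fragments onto a reference genome, builds per-position
    conservation profiles, extracts conserved SNP-free segments,
    predicts amplicons and classifies assay coverage (including
    3'-proximal primer mismatches and double-enhancer duplications),
    enumerates and ranks candidate TaqMan primer/probe sets with
    nearest-neighbor melting temperatures, and computes qPCR
    standard-curve statistics (slope, R-squared, amplification
    efficiency, ENGL acceptance, replicate RSD, LOD/LOQ). A seeded
    synthetic-panel generator with a truth ledger makes the whole
    pipeline testable without any sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
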