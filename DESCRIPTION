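Package: mtcurate
Title: Curation of Multi-Study Mitochondrial Sequence Data for Skyline
    Demographic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assemble comparable mitochondrial DNA datasets from
    sequence records deposited by many independent studies. Parses GenBank
    flat files, standardises gene and organism nomenclature, removes RefSeq
    duplicates, aligns and crops sequences to their maximum overlap,
    collapses haplotypes and audits per-study deposition style, magnifies
    representative haplotypes back to sampled frequencies, builds minimum
    spanning tree haplotype networks, drops divergent singleton outliers,
    applies information-content filters, and emits Bayesian skyline ready
    BEAST2 XML together with trace diagnostics (effective sample size) and
    skyline profile parsing and plotting. Includes a seeded synthetic record
    generator with a ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    yaml,
    seqinr,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
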