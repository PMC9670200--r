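Package: acetydyn
Title: Histone Acetylation Domain Dynamics Across the Mouse Maternal-to-Zygotic Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for charting broad and narrow H3K27ac acetylation-domain
    dynamics across mouse oocyte-to-embryo stages from binned signal tracks:
    cross-stage promoter-anchored signal scaling, threshold-and-merge domain
    calling, stage-transition clustering and enrichment profiles,
    allele-specific signal analysis from SNP-bearing fragments, repeat-family
    pseudo-genome quantification, zygotic genome activation and maternal-decay
    gene-set definitions, and promoter-enhancer Hi-C contact pile-up with
    distance-matched shifted controls. A synthetic-data module generates
    stage- and allele-resolved inputs with a planted ground-truth ledger so
    every analysis stage can be validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
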