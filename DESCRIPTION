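Package: homeokit
Title: Homoeolog-Resolved Transcriptome Analysis for Allopolyploids
Version: 0.1.0
Authors@R:
    person("Homeokit", "Developers", email = "homeokit@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse homoeolog-specific gene expression in an
    allopolyploid species and its two diploid ancestors. Builds a
    homoeologous SNP map from ancestor and hybrid variant calls,
    constructs a virtual second-ancestor genome by allele substitution,
    assigns hybrid RNA-seq reads to their subgenome of origin by
    mismatch comparison, classifies homoeolog groups into additive,
    expression-level-dominant, and transgressive categories with a
    negative-binomial Wald test, estimates homoeolog divergence with
    Nei-Gojobori Ka/Ks, and performs Fisher-exact term enrichment. A
    truth-labelled synthetic allopolyploid data generator makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
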