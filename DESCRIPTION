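Package: nitronet
Title: Integrated lncRNA-miRNA-mRNA Regulatory Network Inference from
    Nitrogen-Response Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds typed lncRNA-miRNA-mRNA regulatory networks from
    replicated expression profiles collected under contrasting nitrogen
    regimes. Provides FPKM/TPM normalization, fold-change plus FDR
    differential-expression calling, positional classification of lncRNA
    loci (lincRNA, intronic, antisense, sense), cis (10 kb window) and
    trans (expression-correlation) lncRNA target prediction, plant-style
    miRNA target complementarity scoring with expression-coherence
    classification, transcription-factor target identification by
    coexpression and promoter binding-element scanning, and assembly of
    the evidence into an exportable network (SIF, GraphML, edge table).
    A negative-binomial simulator with planted regulatory structure
    supplies ground truth so that every stage of the pipeline can be
    scored for edge recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
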