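Package: coevoscan
Title: Correlated Gene-Loss Analysis of Sperm-Signalling Genes Across Metazoa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomic analysis of coevolution among the sperm-specific
    calcium channel CatSper, the sperm-specific sodium/proton exchanger sNHE
    (SLC9C) and the soluble adenylyl cyclase sAC (ADCY10). Provides
    domain-architecture rules for orthologue classification, fewest-event
    (Dollo) gene-loss reconstruction on rooted species trees, phi-coefficient
    correlation of paired loss events with permutation nulls (including an
    exhaustive small-n oracle), six-frame translated scanning for degraded
    pseudogene remnants with colinear exon chaining, alignment site-coverage
    trimming and conservation annotation, curated presence/absence fixtures,
    and seeded synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
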