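Package: CAFGscreen
Title: Screening Cancer-Associated Fibroblast Genes from Paired
    Stroma-Epithelium Expression Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies cancer-associated fibroblast genes (CAFGs) from
    compartment-paired microdissection expression data. Implements
    housekeeping (GAPDH) correction, the stroma-to-epithelium (SE)
    expression ratio with tiered CAFG classification, anchor-marker
    (SPARC) Pearson correlation screening in tumor stroma, cross-cohort
    overlap against reference CAFG lists, and molecular-subtype-restricted
    re-screening. A paired-compartment cohort simulator with planted SE
    ratios, a latent CAF-activation factor and a subtype-specific block
    makes every stage of the pipeline testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: GeneExpression, Microarray, Transcriptomics, Software
RoxygenNote: 7.3.3
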