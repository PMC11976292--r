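Package: epipoly
Title: Epiallele-Based DNA Methylation Heterogeneity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Read-level analysis of DNA methylation disorder in tumours.
    Counts the 16 epiallele patterns at 4-CpG loci (e-loci) from bisulfite
    read-level calls, computes epipolymorphism and average methylation,
    calls differential epipolymorphism between groups with annotation
    enrichment tests, quantifies the contribution of epipolymorphism to
    gene expression beyond average methylation via nested linear models,
    computes intra-tumour heterogeneity indices (APITH, PCAR homogeneity),
    builds and compares phylo-epigenetic and phylogenetic trees, and
    decomposes bulk methylomes into latent methylation components by
    regularized non-negative matrix factorization. A synthetic-data module
    generates multi-region tumour/normal epiallele data, linked expression,
    cell-type mixtures and trees so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
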