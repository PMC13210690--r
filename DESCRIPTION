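Package: bsaqtl
Title: Bulked Segregant Analysis, Fine Mapping and Haplotype Association
    for QTL Discovery
Version: 0.1.0
Authors@R:
    person("bsaqtl", "developers", email = "bsaqtl@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for sequencing-based bulked
    segregant analysis (BSA-seq/QTL-seq) of quantitative traits in
    biparental populations.  Provides variant filtering and parental
    polarization of multi-sample allele-depth tables, three complementary
    per-site association statistics (delta SNP-index, the G statistic with
    tricube G' smoothing, and the fourth-power Euclidean distance), quantile
    thresholding and candidate-region calling with cross-method consensus,
    substitution mapping of recombinant marker profiles, haplotype-phenotype
    association with Duncan's multiple range test, relative expression by
    the 2^-ddCt method, and a seeded synthetic F2 bulk-segregant data
    generator so that every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    S4Vectors,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
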