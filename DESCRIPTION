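Package: snpAssign
Title: Population Assignment of Invasive Pest Specimens from Diagnostic SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for geographic source determination of
    insect pest specimens from biallelic SNP genotypes. Provides a
    SummarizedExperiment-based genotype container with VCF import/export
    and dataset-assembly filters; descriptive population-genetic
    statistics (observed/expected heterozygosity, inbreeding coefficient,
    gene diversity) and Weir-Cockerham F_ST with permutation-tested
    pairwise comparisons; discriminant analysis of principal components
    (DAPC) with cluster discovery, cross-validation and supplemental
    individual prediction; F_ST-ranked diagnostic panel selection with
    scaffold constraints and flanking-sequence extraction for assay
    design; consensus genotype calling from triplicate assay data; and a
    Balding-Nichols synthetic-data generator with a replicate-assay
    error model for validating the whole pipeline against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    vcfR,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
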