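Package: fitnet
Title: Genotypic Fitness Networks and Evolutionary Accessibility from Hybrid Field Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates diploid genotypic fitness networks from hybrid
    field-experiment data and quantifies the evolutionary accessibility and
    ruggedness of adaptive walks between species. Reads biallelic SNP
    genotypes from VCF into 012 dosage form, applies VCFtools-style site
    filters, computes survival/growth/composite hybrid fitness, builds
    genotype networks whose nodes are observed multilocus 012 haplotypes
    and whose edges join mutational neighbours, enumerates accessible
    (monotonically fitness-increasing) paths and fitness peaks, runs
    SNP-subsampling replicate ensembles stratified by the source of
    adaptive variation, and compares ensembles with logistic-regression
    odds ratios, likelihood-ratio tests and FDR correction. A synthetic
    hybrid-swarm generator with exhaustive full-landscape ground truth
    makes every stage verifiable without the original field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
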