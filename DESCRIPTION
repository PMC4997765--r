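Package: pedimpute
Title: Pedigree-Based Genotype Imputation from Sparse Sequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cost-effective whole-genome characterization of pedigreed cohorts by
    combining sparse genotyping-by-sequencing (GBS) panels with inheritance-vector
    based imputation of dense variants from a few whole-genome-sequenced relatives.
    Provides in silico restriction digest and enzyme ranking for GBS panel design,
    framework/dense marker panel construction, an exact multi-meiosis inheritance
    vector HMM and a meiosis-wise MCMC sampler, GIGI-style posterior genotype
    imputation with threshold and most-likely calling, coverage-driven selection of
    individuals for whole-genome sequencing, a gene-dropping simulator with a
    read-depth observation model, and evaluation drivers for accuracy, imputation
    rate and design experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    vcfR,
    seqinr,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
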