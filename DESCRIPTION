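Package: clonescape
Title: Tumor Purity, Clonal Architecture, and Mutation Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates tumor purity and copy-number-alteration (CNA) cell
    fractions from SNP-array B-allele frequencies using a symmetric
    two-component Gaussian mixture fitted by expectation-maximization,
    classifies CNAs and somatic point mutations as clonal or subclonal
    under an explicit mutant-allele-fraction model that accounts for
    purity, copy state, and CNA subclonality, summarizes point-mutation
    signatures (nine substitution types with CpG context, transversion
    and APOBEC TCW fractions), computes per-gene fraction-of-subclonal-
    mutation statistics with exact tests, and performs covariate-adjusted
    CpG-probe methylation association analysis with Bonferroni
    thresholding and annotation-category enrichment. Includes a synthetic
    tumor-genome and methylation-cohort generator providing ground truth
    for parameter-recovery validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cna.R'
    'io.R'
    'methylation.R'
    'pipeline.R'
    'signatures.R'
    'simulate.R'
    'snv.R'
    'utils.R'
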