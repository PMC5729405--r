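Package: polyQTL
Title: Polygenic Mixed-Model eQTL Mapping and Allele-Specific Expression
    Analysis for Structured Cohorts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide mapping of the genetic control of gene expression in
    family-structured cohorts. Implements a polygenic mixed-model expression
    GWAS (score test on the eigenbasis of a genomic kinship matrix), a
    two-level false-discovery-rate correction, conditional pruning of
    linkage-redundant SNPs to lead eQTL-SNPs, and local/distant (cis/trans
    proxy) classification. A companion allele-specific expression caller
    applies exact binomial tests to per-sample allele read counts with
    per-animal FDR correction and cross-animal aggregation, and maps calls to
    genes. Downstream tools build bipartite SNP-gene regulatory networks,
    detect master-regulator loci, and filter co-expression edges with the
    partial correlation and information theory (PCIT) algorithm. A synthetic
    half-sib cohort generator with known cis/trans architecture supports
    power and calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'ase.R'
    'egwas.R'
    'genotype-qc.R'
    'io.R'
    'networks.R'
    'polyQTL-package.R'
    'preprocess.R'
    'simulate.R'
    'studies.R'
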