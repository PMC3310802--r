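Package: archevo
Title: Lineage-Based Evolutionary Dynamics of Protein Domain Architectures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of protein domain architecture
    content across genomes grouped into lineages. Builds canonical N-to-C
    run-length-encoded architecture strings from PfamScan-style domain hit
    tables, aggregates architecture-by-species copy-number ("genomic dosage")
    matrices, classifies architectures into lineage presence/absence patterns
    under a majority-rule prevalence filter, tests lineage-wise dosage
    expansion on log-transformed copy numbers with whole-genome-duplication
    normalization and a max-T step-down bootstrap multiplicity adjustment,
    and classifies domains of lineage-specific architectures as newly
    emerged versus pre-existing with chi-square goodness-of-fit tests. A
    seeded simulator generates multi-genome content with known ground truth
    so every pipeline stage is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ComparativeGenomics, Proteomics, StatisticalMethod, Phylogenetics
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'archevo-package.R'
    'architecture.R'
    'content.R'
    'patterns.R'
    'expansion.R'
    'lineage-io.R'
    'novelty.R'
    'profile.R'
    'simulate.R'
    'pipeline.R'
    'reference-data.R'
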