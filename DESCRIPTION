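Package: snp2drug
Title: Candidate Gene Prioritization at GWAS Risk Loci and Drug-Target
    Overlap Enrichment
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An in-silico pipeline that prioritizes candidate genes at
    genome-wide association study (GWAS) risk loci by a seven-criterion
    binary evidence score (missense consequence, cis-eQTL, text-mining
    and protein-interaction gene p-values, somatic-mutation overlap, and
    knockout-phenotype and functional-term enrichment), tests risk loci
    for overlap with chromatin-mark peaks by permutation, expands the
    prioritized gene set one hop through a protein-protein interaction
    network, and scores the expanded set for enrichment of approved-drug
    targets with exact hypergeometric statistics. Includes a synthetic
    resource-bundle generator with planted ground truth so every stage
    is testable without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
biocViews: GenomeWideAssociation, SNP, NetworkEnrichment, Pharmacogenomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
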