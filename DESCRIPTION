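Package: ontoqtl
Title: Ontology-Guided Refinement of Bulk-Segregant QTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workflow for refining candidate gene lists from
    pooled (bulk-segregant) sequencing of a segregating cross. Reads
    multi-pool VCFs with per-sample allele depths, applies depth and
    genotype-quality filters, computes per-SNP allele-frequency contrasts
    (SNP-index, delta SNP-index, the G likelihood-ratio statistic and its
    tricube-smoothed G' form), derives simulation-based null confidence
    intervals for delta SNP-index, collapses candidate SNPs into QTL
    intervals, intersects them with gene models, classifies coding-sequence
    variant effects (synonymous, missense, start-lost, stop-gained,
    frameshift, splice-site), and narrows the resulting gene set through a
    Gene Ontology-mediated cascade: hypergeometric term enrichment with
    Benjamini-Yekutieli correction per pool contrast, cross-contrast
    merging, pruning of the enriched subgraph beneath an anchor term,
    selection of genes transitively annotated to a focus term, and pathway
    (gene-set) over-representation. A synthetic-data module simulates a
    two-parent cross with a planted causal locus plus toy genome,
    annotation, ontology and pathway fixtures so the whole pipeline is
    testable offline, including parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    vcfR,
    rtracklayer,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
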