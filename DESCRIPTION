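Package: tagatlas
Title: Digital Gene Expression Tag Profiling with DpnII-Anchored Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for SAGE-style digital gene expression (DGE) profiling
    based on 20-base DpnII-anchored transcript tags. Covers the full
    analysis path from raw tag reads to tissue classification: artifact
    filtering and tags-per-million (TPM) normalization, exhaustive
    virtual-tag indexing of a genome on both strands, tag-to-genome
    mapping with single-mismatch and EST rescue of non-mapping tags,
    gene-model annotation (sense/antisense orientation, 3'-terminus site
    ranks, upstream distances, overlapping-gene confounds, mitochondrial
    partition), a named filter cascade over the tag universe, robust
    per-library summary statistics (one-step Huber M-estimator, MAD),
    coefficient-of-variation ranking of constitutively expressed genes,
    and complete-linkage clustering of expression profiles in Aitchison
    simplex geometry. A synthetic-data generator produces genomes, gene
    models and tag libraries with full ground truth so that every stage
    is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    withr,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
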