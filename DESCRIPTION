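Package: regoa
Title: Gene Ontology Annotation of Cis-Regulatory Elements by
    Heterogeneous Network Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates cis-regulatory elements (enhancers and promoters)
    with Gene Ontology terms by assembling a heterogeneous network of GO
    terms, genes, transcription factors and regulatory elements from the
    GO hierarchy, gene annotations, protein-protein interactions and a
    context-specific gene regulatory network; embedding the network with
    meta-path-guided random walks and skip-gram; calibrating a per-term
    cosine-similarity threshold on gene function prediction; and
    intersecting embedding-derived with regulation-derived annotations.
    Includes a binomial enrichment test for genomic region sets against
    the annotated-element background, application drivers for ChIP-seq
    transcription-factor annotation, differential ATAC-seq peaks and
    GWAS trait similarity, and a synthetic planted-community data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
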