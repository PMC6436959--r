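Package: pirnascape
Title: Annotation and Comparative Analysis of Nematode piRNA Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of piRNA (21U-RNA) biogenesis in
    nematode genomes. Annotates piRNA loci from small-RNA mapping sites using
    upstream promoter-motif (Ruby motif) position weight matrix scans with
    thresholds derived from bimodal score distributions; quantifies genomic
    clustering of loci (binomial contig enrichment, span-90 curves, and a
    mixture-of-linear-regressions classifier of clustered versus dispersed
    organisation); relates loci to chromatin domains, genes, introns, promoters
    and expression strata; measures selection on promoter motifs from
    multi-strain SNP panels; and scores promoter-proximal RNA polymerase II
    pausing signals from nearest-neighbour DNA melting-temperature profiles,
    Bayesian Integral Log-Odds (BILD) column scores, and resampling tests on
    capped precursor length distributions. Includes a synthetic-genome
    generator with planted ground truth for end-to-end validation.
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
    Biostrings,
    rtracklayer,
    mclust,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
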