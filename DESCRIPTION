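Package: circfield
Title: Circular RNA Discovery, Differential Expression and Sponge
    Candidate Analysis with a Field-Effect Study Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects head-to-tail back-splice junctions of circular RNAs
    from RNA-seq reads by anchor split-mapping, forms consensus calls
    between two callers, annotates junctions against gene models (host
    gene, origin class, exon count, spliced length and sequence), tests
    differential expression across a three-group no-cancer /
    tumor-adjacent / tumor design with a negative-binomial conditional
    exact test using common and tagwise dispersion and FDR control,
    nominates miRNA-sponge candidates by seed-complement scanning of
    circularized sequences, and performs hypergeometric pathway
    over-representation. Ships a synthetic-study generator (genome, gene
    models, circRNA truth set with field-effect group structure,
    junction-spanning reads, miRNA resources) so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    fgsea,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
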