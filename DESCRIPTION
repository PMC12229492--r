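Package: inversionscape
Title: Harmonization and Gene-Intersection Analysis of Chromosomal Inversion Callsets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the landscape of chromosomal inversions across
    population structural-variant callsets. Harmonizes inversion calls from VCF
    (symbolic <INV> alleles), DGV-style variant tables and BED into a common
    GRanges-backed container; classifies every inversion-gene intersection as
    gene-spanning, gene-disrupting or intragenic with intron/exon context;
    stratifies inversions by allele frequency and derives recessive-disease
    candidate inversions via an OMIM inheritance-mode cascade; quantifies
    cross-dataset redundancy under exact and fractional-overlap criteria; and
    computes length summaries, exact Wilcoxon rank-sum, binomial and
    over-representation statistics. A synthetic-data generator produces
    genomes, gene models, annotations and callsets with planted ground truth
    emulating the length and allele-frequency structure of public datasets, so
    the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
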